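#' Free effect terms of an item under an attribute hierarchy
#'
#' The log-linear measurement model gives each item an intercept plus one
#' effect per nonempty subset of its measured attributes (main effects and
#' interactions). When attributes are hierarchically related the permissible
#' profile space shrinks and some effect columns become linearly dependent
#' over it; those redundant parameters are fixed at zero in the hierarchical
#' model. This function returns the retained ("free") subsets.
#'
#' Candidates are screened greedily for linear independence of their
#' indicator columns over the permissible profile space (the intercept column
#' is always included first). Candidate order: subsets that are closed under
#' the prerequisite relation restricted to the item's measured attributes are
#' tried first (ascending size, then lexicographic), then the remaining
#' subsets in the same order. With this ordering a fully hierarchical item
#' retains exactly the prerequisite-closed chains (e.g. for q = (1,1,1) under
#' the linear hierarchy: the main effect of attribute 1, the 1x2 interaction
#' and the 1x2x3 interaction — four free parameters with the intercept),
#' while under independent attributes all 2^m - 1 subsets of the m measured
#' attributes are retained.
#'
#' @param q_vector Binary length-K q-vector (must be nonzero).
#' @param hierarchy An `attribute_hierarchy`.
#' @param space Optional pre-computed `profile_space` for the hierarchy.
#' @return A list of integer vectors, each a free attribute subset (1-based,
#'   ascending), in retention order.
#' @export
active_terms <- function(q_vector, hierarchy, space = NULL) {
  stopifnot(inherits(hierarchy, "attribute_hierarchy"))
  K <- hierarchy$n_attributes
  if (length(q_vector) != K) stop("q_vector length does not match K")
  measured <- which(q_vector == 1)
  if (length(measured) == 0L) stop("q_vector is all zero")
  space <- space %||% profile_space(hierarchy)
  R <- reachability_matrix(hierarchy)
  P <- space$profiles

  # combn(x, m) treats a length-1 numeric x as seq_len(x); guard that case
  subsets <- if (length(measured) == 1L) list(measured)
  else {
    out <- list()
    for (s in seq_along(measured))
      out <- c(out, utils::combn(measured, s, simplify = FALSE))
    out
  }
  # closed within the measured set: every measured prerequisite of a member
  # is itself a member
  closed <- vapply(subsets, function(S) {
    pre <- unique(unlist(lapply(S, function(k) which(R[, k] == 1L))))
    all(intersect(pre, measured) %in% S)
  }, logical(1L))
  ord <- order(!closed, lengths(subsets))
  subsets <- subsets[ord]

  basis <- matrix(1, nrow(P), 1L) # intercept
  keep <- list()
  for (S in subsets) {
    col <- apply(P[, S, drop = FALSE], 1L, prod)
    trial <- cbind(basis, col)
    if (qr(trial)$rank == ncol(trial)) {
      basis <- trial
      keep <- c(keep, list(S))
    }
  }
  keep
}

subset_key <- function(S) paste(S, collapse = ",")

#' Item parameter sets
#'
#' Builds the per-item parameter structure of the (hierarchical) log-linear
#' measurement model: an intercept (logit units) plus one coefficient per free
#' effect subset from [active_terms()]. Effects for subsets not retained are
#' structurally zero.
#'
#' @param intercept Intercept on the logit scale.
#' @param effects Named numeric vector of effect values; names are free
#'   subsets as comma-joined 1-based attribute indices (e.g. `"1"`, `"1,2"`).
#' @param subsets List of integer vectors matching `effects`.
#' @return An object of class `item_params`.
#' @keywords internal
new_item_params <- function(intercept, effects, subsets) {
  stopifnot(length(effects) == length(subsets))
  names(effects) <- vapply(subsets, subset_key, character(1L))
  structure(list(intercept = intercept, effects = effects, subsets = subsets),
            class = "item_params")
}

#' Study-scheme item parameters for a Q-matrix
#'
#' Assigns every item the fixed parameter scheme used in the simulation
#' study: intercept -1, every free main effect 2, every free interaction
#' (any order) 1, with the free set determined by [active_terms()] under the
#' given hierarchy. Under this scheme an examinee mastering nothing answers
#' correctly with probability `plogis(-1)` (about 0.269) on every item, and
#' an examinee mastering everything with probability at least `plogis(1)`
#' (about 0.731).
#'
#' @param q A `qmatrix`.
#' @param hierarchy An `attribute_hierarchy`.
#' @param intercept,main_effect,interaction Scheme values; defaults -1, 2, 1.
#' @return A list of `item_params`, one per item.
#' @export
default_study_params <- function(q, hierarchy, intercept = -1,
                                 main_effect = 2, interaction = 1) {
  stopifnot(inherits(q, "qmatrix"))
  space <- profile_space(hierarchy)
  lapply(seq_len(nrow(q$entries)), function(i) {
    subsets <- active_terms(q$entries[i, ], hierarchy, space)
    vals <- vapply(subsets, function(S)
      if (length(S) == 1L) main_effect else interaction, numeric(1L))
    new_item_params(intercept, vals, subsets)
  })
}

#' @export
print.item_params <- function(x, ...) {
  cat("Item parameters: intercept =", format(x$intercept), "\n")
  if (length(x$effects))
    cat("  effects:", paste0("{", names(x$effects), "}=",
                             format(x$effects), collapse = ", "), "\n")
  invisible(x)
}

#' Linear predictor and correct-response probability of an item
#'
#' `linear_predictor()` evaluates the item's log-odds of a correct response
#' for a given attribute profile: the intercept plus the sum of effects whose
#' attribute subsets are fully mastered. `prob_correct()` applies the
#' logistic transform.
#'
#' @param params An `item_params`.
#' @param profile Binary length-K attribute profile.
#' @return A scalar logit (`linear_predictor`) or probability in (0, 1)
#'   (`prob_correct`).
#' @examples
#' p <- new_item_params(-1, c(2, 1, 1), list(1L, c(1L, 2L), c(1L, 2L, 3L)))
#' linear_predictor(p, c(1, 1, 1)) # 3
#' prob_correct(p, c(0, 0, 0))     # plogis(-1)
#' @export
linear_predictor <- function(params, profile) {
  stopifnot(inherits(params, "item_params"))
  eta <- params$intercept
  for (j in seq_along(params$subsets)) {
    S <- params$subsets[[j]]
    if (max(S) > length(profile)) stop("profile shorter than effect subsets")
    if (all(profile[S] == 1)) eta <- eta + params$effects[[j]]
  }
  eta
}

#' @rdname linear_predictor
#' @export
prob_correct <- function(params, profile) {
  stats::plogis(linear_predictor(params, profile))
}

# C x p design matrix (intercept first) of an item's free terms over a space
item_design_matrix <- function(subsets, profiles) {
  X <- matrix(1, nrow(profiles), 1L + length(subsets))
  for (j in seq_along(subsets))
    X[, j + 1L] <- apply(profiles[, subsets[[j]], drop = FALSE], 1L, prod)
  X
}

# I x C matrix of correct-response probabilities over a profile space
item_prob_matrix <- function(item_params, space) {
  P <- space$profiles
  t(vapply(item_params, function(ip) {
    X <- item_design_matrix(ip$subsets, P)
    as.vector(stats::plogis(X %*% c(ip$intercept, ip$effects)))
  }, numeric(nrow(P))))
}
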