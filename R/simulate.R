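#' Define a simulation study condition
#'
#' A study design bundles everything needed to generate longitudinal
#' diagnostic response data for one condition: the attribute hierarchy, a
#' Q-matrix (a canonical design id or an explicit `qmatrix`), the numbers of
#' examinees, items and time points, the item-parameter scheme, and the
#' learning kernel. Defaults reproduce the study conditions: K = 3
#' attributes, 10 items, N = 1000 examinees, T = 3 time points, item scheme
#' intercept -1 / main effect 2 / interaction 1, uniform initial profiles
#' over the permissible space, and an attribute-gain kernel with
#' `p_gain = 0.4` (each unmastered attribute whose prerequisites were
#' mastered at the previous time point is gained independently with this
#' probability; mastery is never lost).
#'
#' @param hierarchy An `attribute_hierarchy` or a shape name
#'   (`"independent"`, `"divergent"`, `"linear"`).
#' @param design A design id (`"Q1"`, `"Q2"`, `"Q3"`) or an explicit
#'   `qmatrix`.
#' @param n_items,n_examinees,n_times Test length I, sample size N and
#'   number of time points T.
#' @param p_gain Per-attribute gain probability of the learning kernel.
#' @param intercept,main_effect,interaction Item-parameter scheme.
#' @return An object of class `study_design` with the resolved `hierarchy`,
#'   `space`, `qmatrix`, `item_params`, `delta` (uniform), `tau` (kernel
#'   transition matrix) and the scalar settings.
#' @export
study_design <- function(hierarchy = "linear", design = "Q2",
                         n_items = 10L, n_examinees = 1000L, n_times = 3L,
                         p_gain = 0.4, intercept = -1, main_effect = 2,
                         interaction = 1) {
  if (is.character(hierarchy)) hierarchy <- hierarchy_shape(hierarchy)
  stopifnot(inherits(hierarchy, "attribute_hierarchy"))
  space <- profile_space(hierarchy)
  q <- if (inherits(design, "qmatrix")) design
       else build_design(hierarchy, design, n_items)
  structure(list(
    hierarchy = hierarchy,
    space = space,
    qmatrix = q,
    design_id = if (is.character(design)) design else "custom",
    n_items = nrow(q$entries),
    n_examinees = as.integer(n_examinees),
    n_times = as.integer(n_times),
    p_gain = p_gain,
    item_params = default_study_params(q, hierarchy, intercept, main_effect,
                                       interaction),
    delta = rep(1 / space$n_profiles, space$n_profiles),
    tau = kernel_to_transitions(space, p_gain)
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", x$hierarchy$label, "hierarchy x", x$design_id,
      "| N =", x$n_examinees, ", I =", x$n_items, ", T =", x$n_times,
      ", C =", x$space$n_profiles, ", p_gain =", x$p_gain, "\n")
  invisible(x)
}

#' Transition matrix implied by the attribute-gain kernel
#'
#' The generating learning process gains each unmastered attribute whose
#' prerequisites were all mastered at the previous time point independently
#' with probability `p_gain`; mastery is never lost. The implied transition
#' matrix over the permissible profile space is therefore upper triangular in
#' the mastery partial order, with `P(dest | src) = p_gain^g (1-p_gain)^(e-g)`
#' where e is the number of eligible attributes at `src` and g the number
#' gained; the full-mastery profile is absorbing.
#'
#' @param space A `profile_space`.
#' @param p_gain Gain probability in \[0, 1\].
#' @return A C x C row-stochastic matrix.
#' @examples
#' s <- profile_space(hierarchy_shape("linear", 3))
#' kernel_to_transitions(s, 0.4)["110", "111"] # 0.4
#' @export
kernel_to_transitions <- function(space, p_gain) {
  stopifnot(inherits(space, "profile_space"), p_gain >= 0, p_gain <= 1)
  P <- space$profiles
  C <- nrow(P)
  K <- ncol(P)
  R <- reachability_matrix(space$hierarchy)
  tau <- matrix(0, C, C, dimnames = list(rownames(P), rownames(P)))
  for (r in seq_len(C)) {
    src <- P[r, ]
    eligible <- which(src == 0 &
                      vapply(seq_len(K), function(k)
                        all(src[setdiff(which(R[, k] == 1L), k)] == 1),
                        logical(1L)))
    for (c in seq_len(C)) {
      dst <- P[c, ]
      gained <- which(dst == 1 & src == 0)
      if (any(dst < src) || !all(gained %in% eligible)) next
      g <- length(gained)
      tau[r, c] <- p_gain^g * (1 - p_gain)^(length(eligible) - g)
    }
  }
  tau
}

#' Sample true attribute-profile trajectories
#'
#' Draws time-1 profiles uniformly over the permissible space, then evolves
#' each examinee through the design's transition matrix.
#'
#' @param design A `study_design`.
#' @param seed Integer seed (all randomness in the draw).
#' @return An N x T integer matrix of canonical profile indices (1-based
#'   into `design$space$profiles`).
#' @export
sample_trajectories <- function(design, seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  set.seed(seed)
  N <- design$n_examinees
  Tt <- design$n_times
  C <- design$space$n_profiles
  traj <- matrix(0L, N, Tt)
  traj[, 1L] <- sample.int(C, N, replace = TRUE, prob = design$delta)
  for (t in seq_len(Tt - 1L)) {
    for (r in seq_len(C)) {
      idx <- which(traj[, t] == r)
      if (length(idx))
        traj[idx, t + 1L] <- sample.int(C, length(idx), replace = TRUE,
                                        prob = design$tau[r, ])
    }
  }
  traj
}

#' Generate dichotomous item responses for given trajectories
#'
#' Independent Bernoulli draws with the item response probabilities of the
#' measurement model evaluated at each examinee's true profile; item
#' parameters are identical at every time point (time invariance).
#'
#' @param trajectories N x T matrix of profile indices, as from
#'   [sample_trajectories()].
#' @param item_params List of `item_params`, one per item.
#' @param space The `profile_space` the indices refer to.
#' @param seed Integer seed.
#' @return An N x I x T binary array of responses.
#' @export
generate_responses <- function(trajectories, item_params, space, seed = 1L) {
  stopifnot(inherits(space, "profile_space"))
  set.seed(seed)
  N <- nrow(trajectories)
  Tt <- ncol(trajectories)
  I <- length(item_params)
  p <- item_prob_matrix(item_params, space) # I x C
  y <- array(0L, dim = c(N, I, Tt))
  for (t in seq_len(Tt)) {
    probs <- t(p[, trajectories[, t], drop = FALSE]) # N x I
    y[, , t] <- (matrix(stats::runif(N * I), N, I) < probs) * 1L
  }
  y
}

#' Simulate one complete study data set
#'
#' Convenience wrapper: samples trajectories and responses under a design.
#' The trajectory and response draws use `seed` and `seed + 500000L`
#' respectively, so a single integer reproduces the whole data set.
#'
#' @param design A `study_design`.
#' @param seed Integer base seed.
#' @return A list with `responses` (N x I x T array), `truth` (N x T profile
#'   index matrix), `design` and `seed`.
#' @export
simulate_study <- function(design, seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  truth <- sample_trajectories(design, seed)
  responses <- generate_responses(truth, design$item_params, design$space,
                                  seed + 500000L)
  list(responses = responses, truth = truth, design = design, seed = seed)
}
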