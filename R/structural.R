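#' Initial prevalence and transition containers
#'
#' The structural half of the longitudinal model consists of the initial
#' profile prevalence (delta, a length-C probability vector over the
#' permissible profile space at time 1) and one C x C row-stochastic
#' transition matrix per adjacent pair of time points (tau). These helpers
#' validate the containers used throughout estimation and simulation.
#'
#' @param delta Nonnegative length-C vector summing to 1 (tolerance 1e-10).
#' @return The validated object.
#' @keywords internal
check_prevalence <- function(delta) {
  if (any(delta < 0) || abs(sum(delta) - 1) > 1e-10)
    stop("delta must be a probability vector summing to 1")
  delta
}

check_transition <- function(tau) {
  tau <- as.matrix(tau)
  if (nrow(tau) != ncol(tau)) stop("transition matrix must be square")
  if (any(tau < 0) || any(abs(rowSums(tau) - 1) > 1e-10))
    stop("transition matrix rows must be probabilities summing to 1")
  tau
}

#' Convert multinomial-logit transition parameters to probabilities
#'
#' The transition between adjacent time points can be written as a
#' multinomial regression on dummy coding of the previous profile: with
#' destination class 1 (the first canonical profile) as reference, the
#' log-odds of destination c vs the reference from source r is
#' `a[c] + b[r, c]` (and `b[1, ] = 0` for the reference source). A `-Inf`
#' logit encodes a structurally forbidden (masked) cell and maps to an exact
#' zero probability.
#'
#' @param intercepts Length C-1 vector `a` (destinations 2..C).
#' @param coefs (C-1) x (C-1) matrix `b` (rows: sources 2..C, columns:
#'   destinations 2..C). Cells masked out by `mask` may be `NA`.
#' @param mask Optional C x C binary matrix; cells with 0 are structurally
#'   forbidden and receive probability exactly 0. The reference column
#'   (destination 1) must be allowed in every row.
#' @return A C x C row-stochastic matrix.
#' @examples
#' transition_from_logits(rep(0, 3), matrix(0, 3, 3)) # uniform 4 x 4
#' @export
transition_from_logits <- function(intercepts, coefs, mask = NULL) {
  Cm1 <- length(intercepts)
  coefs <- as.matrix(coefs)
  if (!all(dim(coefs) == Cm1))
    stop("coefs must be a square matrix of order length(intercepts)")
  C <- Cm1 + 1L
  if (is.null(mask)) mask <- matrix(1, C, C)
  check_mask(mask, C)
  logits <- matrix(0, C, C)
  logits[1L, -1L] <- intercepts
  logits[-1L, -1L] <- sweep(coefs, 2L, intercepts, "+")
  logits[mask == 0] <- -Inf
  if (anyNA(logits)) stop("NA logit in an unmasked cell")
  w <- exp(logits - apply(logits, 1L, max))
  w / rowSums(w)
}

check_mask <- function(mask, C) {
  if (!all(dim(as.matrix(mask)) == C)) stop("mask must be C x C")
  if (any(mask[, 1L] == 0))
    stop("the reference destination (class 1) cannot be masked")
  invisible(mask)
}

#' Recover multinomial-logit parameters from a transition matrix
#'
#' Inverse of [transition_from_logits()]. All unmasked entries must be
#' positive and the reference column (destination 1) must be positive in
#' every row; a zero entry is an error unless the corresponding `mask` cell
#' is 0, in which case the cell is excluded from the inversion (its
#' coefficient is `NA`, and an intercept whose reference-row cell is masked
#' is set to 0 by convention). The round trip through
#' [transition_from_logits()] reproduces the matrix to within 1e-10.
#'
#' @param tau C x C row-stochastic matrix.
#' @param mask Optional C x C binary matrix of structurally allowed cells.
#' @return A list with `intercepts` (length C-1), `coefs` ((C-1) x (C-1),
#'   `NA` at masked cells) and `mask`.
#' @export
logits_from_transition <- function(tau, mask = NULL) {
  tau <- check_transition(tau)
  C <- nrow(tau)
  if (is.null(mask)) mask <- matrix(1, C, C)
  check_mask(mask, C)
  if (any(tau[, 1L] <= 0))
    stop("destination class 1 is the reference and must have positive ",
         "probability from every source")
  if (any(tau[mask == 1] <= 0))
    stop("zero transition probability in an unmasked cell: its logit is ",
         "undefined (supply a mask)")
  logits <- log(tau) - log(tau[, 1L])
  intercepts <- ifelse(mask[1L, -1L] == 0, 0, logits[1L, -1L])
  coefs <- sweep(logits[-1L, -1L, drop = FALSE], 2L, intercepts, "-")
  coefs[mask[-1L, -1L, drop = FALSE] == 0] <- NA_real_
  list(intercepts = intercepts, coefs = coefs, mask = mask)
}

#' Restrict a transition matrix to hierarchy-consistent moves
#'
#' The transition matrices of the hierarchical model are defined over the
#' permissible profile space by construction. Optionally, backward moves
#' (losing mastery) can be forbidden: destinations that do not dominate the
#' source componentwise get probability zero and each row is renormalised.
#' The self-transition is always allowed, so no row can become empty.
#'
#' @param tau C x C row-stochastic matrix over `space`.
#' @param space A `profile_space`.
#' @param forbid_regression If `TRUE`, zero out mastery-losing destinations.
#' @return A C x C row-stochastic matrix.
#' @export
apply_hierarchy_constraints <- function(tau, space, forbid_regression = FALSE) {
  stopifnot(inherits(space, "profile_space"))
  tau <- check_transition(tau)
  if (nrow(tau) != space$n_profiles)
    stop("transition matrix order does not match the profile space")
  if (!forbid_regression) return(tau)
  keep <- transition_support(space)
  tau <- tau * keep
  tau <- tau / rowSums(tau)
  dimnames(tau) <- list(rownames(space$profiles), rownames(space$profiles))
  tau
}

# C x C indicator of componentwise dominance: dest >= src
transition_support <- function(space) {
  P <- space$profiles
  C <- nrow(P)
  keep <- matrix(0L, C, C)
  for (r in seq_len(C))
    keep[r, ] <- as.integer(P %*% P[r, ] == sum(P[r, ]))
  keep
}
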