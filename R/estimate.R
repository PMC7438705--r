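#' Assemble a longitudinal diagnostic classification model
#'
#' Bundles the measurement and structural parameter blocks of a (possibly
#' hierarchical) transition diagnostic classification model: a Q-matrix,
#' time-invariant item parameters, an initial profile prevalence `delta` and
#' one transition matrix per adjacent pair of time points. Under
#' `variant = "tdcm"` the latent space is the full set of 2^K profiles and no
#' measurement parameters are masked, regardless of the hierarchy supplied;
#' under `variant = "htdcm"` the permissible space and the zero masks are
#' derived from the hierarchy.
#'
#' @param qmatrix A `qmatrix`.
#' @param hierarchy An `attribute_hierarchy`.
#' @param item_params List of `item_params`, one per item (free subsets must
#'   match the variant's masks; see [active_terms()]).
#' @param delta Length-C initial prevalence vector.
#' @param tau A single C x C transition matrix (recycled across the T-1
#'   transitions) or a list of T-1 matrices.
#' @param n_times Number of time points T.
#' @param variant `"htdcm"` or `"tdcm"`.
#' @param forbid_regression If `TRUE`, mastery-losing transitions are
#'   structurally zero.
#' @return An object of class `tdcm_model`.
#' @export
tdcm_model <- function(qmatrix, hierarchy, item_params, delta, tau,
                       n_times, variant = c("htdcm", "tdcm"),
                       forbid_regression = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(qmatrix, "qmatrix"), inherits(hierarchy, "attribute_hierarchy"))
  model_h <- if (variant == "tdcm")
    attribute_hierarchy(hierarchy$n_attributes) else hierarchy
  space <- profile_space(model_h)
  C <- space$n_profiles
  n_times <- as.integer(n_times)
  if (!is.list(tau)) tau <- rep(list(tau), n_times - 1L)
  if (length(tau) != n_times - 1L)
    stop("need one transition matrix per adjacent pair of time points")
  tau <- lapply(tau, check_transition)
  if (any(vapply(tau, nrow, 1L) != C) || length(delta) != C)
    stop("delta/tau dimensions do not match the profile space (C = ", C, ")")
  check_prevalence(delta)
  if (length(item_params) != nrow(qmatrix$entries))
    stop("need one item_params per Q-matrix row")
  structure(list(
    qmatrix = qmatrix, hierarchy = model_h, space = space,
    item_params = item_params, delta = delta, tau = tau,
    n_times = n_times, variant = variant,
    forbid_regression = forbid_regression
  ), class = "tdcm_model")
}

#' @export
print.tdcm_model <- function(x, ...) {
  cat(toupper(x$variant), "model:", nrow(x$qmatrix$entries), "items,",
      x$space$n_attributes, "attributes,", x$space$n_profiles, "profiles,",
      x$n_times, "time points,", count_free_parameters(x), "free parameters\n")
  invisible(x)
}

#' Number of free parameters of a model
#'
#' Item free effects (+ intercepts) plus C - 1 initial-prevalence parameters
#' plus, for each transition matrix, one fewer free cell per row than its
#' structural support (masked cells are not counted).
#'
#' @param model A `tdcm_model`.
#' @return Integer count.
#' @export
count_free_parameters <- function(model) {
  stopifnot(inherits(model, "tdcm_model"))
  n_item <- sum(vapply(model$item_params,
                       function(ip) 1L + length(ip$effects), integer(1L)))
  C <- model$space$n_profiles
  support <- if (model$forbid_regression)
    transition_support(model$space) else matrix(1L, C, C)
  n_tau <- (model$n_times - 1L) * sum(rowSums(support) - 1L)
  n_item + (C - 1L) + n_tau
}

check_responses <- function(responses, n_items = NULL, n_times = NULL) {
  if (!is.array(responses) || length(dim(responses)) != 3L)
    stop("responses must be an N x I x T array (see read_responses_long)")
  if (anyNA(responses))
    stop("missing responses are not supported: complete data required")
  if (!all(responses %in% c(0L, 1L))) stop("responses must be 0/1")
  d <- dim(responses)
  if (!is.null(n_items) && d[2L] != n_items)
    stop("responses have ", d[2L], " items but the model has ", n_items)
  if (!is.null(n_times) && d[3L] != n_times)
    stop("responses have ", d[3L], " time points but the model has ", n_times)
  invisible(responses)
}

# N x C x T array of log measurement likelihoods log P(y_nt | profile c).
# Probabilities are clamped away from 0/1 so that extreme (near-deterministic)
# item parameters cannot produce 0 * -Inf = NaN in the matrix products.
response_log_lik <- function(responses, p) {
  d <- dim(responses)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  logp <- log(p); log1mp <- log1p(-p) # I x C
  out <- array(0, dim = c(d[1L], ncol(p), d[3L]))
  for (t in seq_len(d[3L])) {
    Yt <- matrix(responses[, , t], d[1L], d[2L])
    out[, , t] <- Yt %*% logp + (1 - Yt) %*% log1mp
  }
  out
}

# scaled forward-backward; returns per-examinee loglik, marginal posteriors
# gamma (N x C x T) and pairwise posteriors xi (list of N x C x C)
forward_backward <- function(delta, tau, logB) {
  N <- dim(logB)[1L]; C <- dim(logB)[2L]; Tt <- dim(logB)[3L]
  bmax <- apply(logB, c(1L, 3L), max)              # N x T
  B <- array(0, dim = dim(logB))
  for (t in seq_len(Tt)) B[, , t] <- exp(logB[, , t] - bmax[, t])
  alpha <- array(0, dim = c(N, C, Tt))
  cs <- matrix(0, N, Tt)                            # scaling constants
  a <- sweep(matrix(B[, , 1L], N, C), 2L, delta, "*")
  cs[, 1L] <- rowSums(a)
  alpha[, , 1L] <- a / cs[, 1L]
  for (t in seq_len(Tt - 1L)) {
    a <- (matrix(alpha[, , t], N, C) %*% tau[[t]]) * matrix(B[, , t + 1L], N, C)
    cs[, t + 1L] <- rowSums(a)
    alpha[, , t + 1L] <- a / cs[, t + 1L]
  }
  loglik_n <- rowSums(log(cs)) + rowSums(bmax)
  beta <- array(0, dim = c(N, C, Tt))
  beta[, , Tt] <- 1
  xi <- vector("list", Tt - 1L)
  for (t in rev(seq_len(Tt - 1L))) {
    D <- matrix(B[, , t + 1L], N, C) * matrix(beta[, , t + 1L], N, C)
    beta[, , t] <- (D %*% t(tau[[t]])) / cs[, t + 1L]
    x <- array(0, dim = c(N, C, C))
    at <- matrix(alpha[, , t], N, C)
    Dn <- D / cs[, t + 1L]
    for (r in seq_len(C))
      x[, r, ] <- at[, r] * sweep(Dn, 2L, tau[[t]][r, ], "*")
    xi[[t]] <- x
  }
  gamma <- alpha * beta
  list(loglik = sum(loglik_n), loglik_n = loglik_n, gamma = gamma, xi = xi)
}

#' Marginal log-likelihood of a model
#'
#' Sum over examinees of the log of the marginal probability of each response
#' matrix, with the latent trajectory integrated out by the forward
#' recursion (complexity N T C^2 + N T C I); mathematically identical to
#' summing the structural-times-measurement product over all C^T latent
#' trajectories. Computed in log space, so valid inputs never produce NaN.
#'
#' @param model A `tdcm_model`.
#' @param responses N x I x T binary array.
#' @return Scalar log-likelihood.
#' @export
loglik_tdcm <- function(model, responses) {
  stopifnot(inherits(model, "tdcm_model"))
  check_responses(responses, nrow(model$qmatrix$entries), model$n_times)
  logB <- response_log_lik(responses, item_prob_matrix(model$item_params,
                                                       model$space))
  forward_backward(model$delta, model$tau, logB)$loglik
}

#' E-step: posterior distributions over latent profiles
#'
#' Runs the forward-backward algorithm and returns, for every examinee, the
#' marginal posterior over profiles at each time point (`gamma`, N x C x T)
#' and the pairwise posterior over adjacent-time profile pairs (`xi`, a list
#' of T-1 arrays N x C x C), together with the log-likelihood. Each `gamma`
#' and `xi` slice sums to 1 per examinee, and marginalising `xi` over its
#' source (destination) index recovers `gamma` at t+1 (t).
#'
#' @inheritParams loglik_tdcm
#' @return A list of class `tdcm_posteriors` with `gamma`, `xi`, `loglik`,
#'   `loglik_n`.
#' @export
e_step <- function(model, responses) {
  stopifnot(inherits(model, "tdcm_model"))
  check_responses(responses, nrow(model$qmatrix$entries), model$n_times)
  logB <- response_log_lik(responses, item_prob_matrix(model$item_params,
                                                       model$space))
  fb <- forward_backward(model$delta, model$tau, logB)
  structure(fb[c("gamma", "xi", "loglik", "loglik_n")],
            class = "tdcm_posteriors")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# one weighted-logistic item update on the collapsed profile-level data:
# successes S (length C), totals W (length C), design X (C x p).
update_item_params <- function(ip, X, S, W, monotone, env) {
  beta0 <- c(ip$intercept, ip$effects)
  p <- length(beta0)
  lower <- c(-25, rep(if (monotone) 0 else -25, p - 1L))
  upper <- rep(25, p)
  fit1 <- optim_item(beta0, X, S, W, lower, upper, ridge = 1e-8)
  beta <- fit1$par
  if (any(abs(beta) >= 25 - 1e-6)) {
    if (!env$ridge_warned) {
      warning("quasi-separation in an item update; applying ridge penalty 1e-4",
              call. = FALSE)
      env$ridge_warned <- TRUE
    }
    fit1 <- optim_item(beta0, X, S, W, lower, upper, ridge = 1e-4)
    beta <- fit1$par
  }
  new_item_params(beta[1L], beta[-1L], ip$subsets)
}

optim_item <- function(beta0, X, S, W, lower, upper, ridge) {
  nll <- function(b) {
    eta <- as.vector(X %*% b)
    sum(W * softplus(eta)) - sum(S * eta) + ridge * sum(b^2) / 2
  }
  gr <- function(b) {
    eta <- as.vector(X %*% b)
    as.vector(crossprod(X, W * stats::plogis(eta) - S)) + ridge * b
  }
  res <- stats::optim(beta0, nll, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 100L))
  if (res$value > nll(beta0)) res$par <- beta0 # never move downhill in Q
  res
}

#' M-step: parameter updates from posterior expectations
#'
#' Closed-form updates for the initial prevalence (normalised time-1
#' posterior mass) and the transition matrices (normalised pairwise posterior
#' mass, with structurally masked cells forced to zero before
#' renormalisation), and weighted logistic updates for each item's free
#' parameters on the profile-collapsed expected data. With
#' `monotone = TRUE` (the default in fitting) all non-intercept effects are
#' constrained to be nonnegative, which keeps every item's response
#' probability nondecreasing in mastery.
#'
#' @param posteriors A `tdcm_posteriors` from [e_step()].
#' @param responses The N x I x T response array.
#' @param model The current `tdcm_model`.
#' @param monotone Constrain effects to be nonnegative.
#' @return An updated `tdcm_model`.
#' @export
m_step <- function(posteriors, responses, model, monotone = TRUE) {
  stopifnot(inherits(posteriors, "tdcm_posteriors"),
            inherits(model, "tdcm_model"))
  N <- dim(responses)[1L]
  C <- model$space$n_profiles
  Tt <- model$n_times
  gamma <- posteriors$gamma

  delta <- colSums(matrix(gamma[, , 1L], N, C)) / N

  support <- if (model$forbid_regression)
    transition_support(model$space) else matrix(1L, C, C)
  tau <- vector("list", Tt - 1L)
  for (t in seq_len(Tt - 1L)) {
    Xi <- apply(posteriors$xi[[t]], c(2L, 3L), sum) * support
    rs <- rowSums(Xi)
    new_t <- model$tau[[t]]
    ok <- rs > 1e-300
    new_t[ok, ] <- Xi[ok, , drop = FALSE] / rs[ok]
    tau[[t]] <- new_t
  }

  W <- numeric(C)
  for (t in seq_len(Tt)) W <- W + colSums(matrix(gamma[, , t], N, C))
  I <- dim(responses)[2L]
  S <- matrix(0, I, C)
  for (t in seq_len(Tt))
    S <- S + crossprod(matrix(responses[, , t], N, I),
                       matrix(gamma[, , t], N, C))
  env <- new.env()
  env$ridge_warned <- FALSE
  P <- model$space$profiles
  item_params <- lapply(seq_len(I), function(i) {
    X <- item_design_matrix(model$item_params[[i]]$subsets, P)
    update_item_params(model$item_params[[i]], X, S[i, ], W, monotone, env)
  })

  model$delta <- delta
  model$tau <- tau
  model$item_params <- item_params
  model
}

random_start <- function(model, monotone) {
  C <- model$space$n_profiles
  d <- stats::rgamma(C, 1)
  model$delta <- d / sum(d)
  support <- if (model$forbid_regression)
    transition_support(model$space) else matrix(1L, C, C)
  model$tau <- lapply(model$tau, function(tt) {
    m <- matrix(stats::rgamma(C * C, 1), C, C) * support
    m / rowSums(m)
  })
  model$item_params <- lapply(model$item_params, function(ip) {
    eff <- stats::rnorm(length(ip$effects), 1, 0.25)
    if (monotone) eff <- abs(eff)
    new_item_params(stats::rnorm(1L, -1, 0.25), eff, ip$subsets)
  })
  model
}

em_run <- function(model, responses, max_iter, tol, monotone) {
  trace <- numeric(0)
  post <- e_step(model, responses)
  ll <- post$loglik
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    model <- m_step(post, responses, model, monotone = monotone)
    post <- e_step(model, responses)
    trace <- c(trace, post$loglik)
    if (abs(post$loglik - ll) / (abs(ll) + 1e-10) < tol) {
      converged <- TRUE
      ll <- post$loglik
      break
    }
    ll <- post$loglik
  }
  list(model = model, loglik = ll, trace = trace, converged = converged,
       posteriors = post)
}

#' Fit a (hierarchical) transition diagnostic classification model
#'
#' Marginal maximum likelihood estimation by EM: the E-step computes exact
#' posteriors over latent profile trajectories with the forward-backward
#' algorithm; the M-step updates the initial prevalence and transition
#' matrices in closed form and each item's free log-linear parameters by a
#' constrained weighted logistic solve. Multiple random starts are run for a
#' short burn-in and the best is continued to convergence; everything is
#' reproducible from `seed`.
#'
#' @param responses N x I x T binary array ([read_responses_long()] builds
#'   one from long CSV data).
#' @param qmatrix A `qmatrix`.
#' @param hierarchy An `attribute_hierarchy` (ignored for the latent space
#'   when `variant = "tdcm"`).
#' @param variant `"htdcm"` (hierarchy-constrained space and item masks) or
#'   `"tdcm"` (full 2^K space, no masks).
#' @param control List of options: `tol` (relative log-likelihood change,
#'   default 1e-6), `max_iter` (500), `n_starts` (5), `seed` (1),
#'   `monotone` (TRUE: non-intercept effects constrained nonnegative),
#'   `forbid_regression` (FALSE), `short_iter` (burn-in iterations per
#'   start, 25).
#' @return An object of class `tdcm_fit`: `model` (the fitted
#'   `tdcm_model`), `logLik`, `trace` (log-likelihood per accepted
#'   iteration, nondecreasing), `converged`, `n_parameters`, `AIC`, `BIC`,
#'   `n_obs`, `seed`, `n_starts`.
#' @examples
#' \donttest{
#' d <- study_design("linear", "Q2", n_examinees = 200)
#' sim <- simulate_study(d, seed = 7)
#' fit <- fit_tdcm(sim$responses, d$qmatrix, d$hierarchy,
#'                 control = list(n_starts = 2, max_iter = 100))
#' fit$logLik
#' }
#' @export
fit_tdcm <- function(responses, qmatrix, hierarchy,
                     variant = c("htdcm", "tdcm"), control = list()) {
  variant <- match.arg(variant)
  ctl <- utils::modifyList(list(tol = 1e-6, max_iter = 500L, n_starts = 5L,
                                seed = 1L, monotone = TRUE,
                                forbid_regression = FALSE, short_iter = 25L),
                           control)
  check_responses(responses)
  d <- dim(responses)
  Tt <- d[3L]
  model_h <- if (variant == "tdcm")
    attribute_hierarchy(hierarchy$n_attributes) else hierarchy
  space <- profile_space(model_h)
  C <- space$n_profiles
  template <- tdcm_model(
    qmatrix, model_h,
    item_params = default_study_params(qmatrix, model_h),
    delta = rep(1 / C, C),
    tau = apply_hierarchy_constraints(matrix(1 / C, C, C), space,
                                      ctl$forbid_regression),
    n_times = Tt, variant = variant,
    forbid_regression = ctl$forbid_regression)

  set.seed(ctl$seed)
  starts <- lapply(seq_len(ctl$n_starts), function(s)
    random_start(template, ctl$monotone))
  short <- lapply(starts, function(m)
    em_run(m, responses, max_iter = min(ctl$short_iter, ctl$max_iter),
           tol = ctl$tol, monotone = ctl$monotone))
  best_i <- which.max(vapply(short, `[[`, numeric(1L), "loglik"))
  best <- short[[best_i]]
  if (!best$converged) {
    cont <- em_run(best$model, responses, max_iter = ctl$max_iter,
                   tol = ctl$tol, monotone = ctl$monotone)
    cont$trace <- c(best$trace, cont$trace)
    best <- cont
  }
  if (!best$converged)
    warning("EM did not converge within max_iter = ", ctl$max_iter,
            call. = FALSE)
  npar <- count_free_parameters(best$model)
  structure(list(
    model = best$model, logLik = best$loglik, trace = best$trace,
    converged = best$converged, n_parameters = npar,
    AIC = -2 * best$loglik + 2 * npar,
    BIC = -2 * best$loglik + log(d[1L]) * npar,
    n_obs = d[1L], seed = ctl$seed, n_starts = ctl$n_starts
  ), class = "tdcm_fit")
}

#' @export
print.tdcm_fit <- function(x, ...) {
  cat("Fitted", toupper(x$model$variant), "| logLik =", format(x$logLik),
      "| parameters =", x$n_parameters,
      "| AIC =", format(round(x$AIC, 1)),
      "| BIC =", format(round(x$BIC, 1)),
      if (x$converged) "| converged" else "| NOT converged", "\n")
  invisible(x)
}

#' @export
logLik.tdcm_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_parameters, class = "logLik")
}

#' MAP classification of examinees
#'
#' Assigns each examinee, at each time point, the permissible profile with
#' maximal marginal posterior probability; ties are broken toward the lower
#' canonical profile index.
#'
#' @param fit A `tdcm_fit` or `tdcm_model`.
#' @param responses The N x I x T response array to classify.
#' @return A list with `profiles` (N x T matrix of canonical profile
#'   indices), `alpha` (N x K x T array of attribute masteries) and
#'   `posterior` (the N x C x T marginal posterior array).
#' @export
classify_profiles <- function(fit, responses) {
  model <- if (inherits(fit, "tdcm_fit")) fit$model else fit
  stopifnot(inherits(model, "tdcm_model"))
  post <- e_step(model, responses)
  N <- dim(post$gamma)[1L]; Tt <- dim(post$gamma)[3L]
  C <- dim(post$gamma)[2L]
  prof <- matrix(0L, N, Tt)
  for (t in seq_len(Tt))
    prof[, t] <- max.col(matrix(post$gamma[, , t], N, C), ties.method = "first")
  K <- model$space$n_attributes
  alpha <- array(0L, dim = c(N, K, Tt))
  for (t in seq_len(Tt))
    alpha[, , t] <- model$space$profiles[prof[, t], , drop = FALSE]
  list(profiles = prof, alpha = alpha, posterior = post$gamma)
}

#' Likelihood-ratio test between nested fits
#'
#' Compares a constrained model (e.g. the hierarchical H-TDCM) against the
#' model it is nested in (e.g. the unconstrained TDCM) fitted to the same
#' data: statistic 2 (logLik_full - logLik_nested), clipped at zero, referred
#' to a chi-square with degrees of freedom equal to the difference in free
#' parameter counts. Regularity can fail when constrained parameters lie on
#' the boundary (e.g. transition probabilities estimated at zero); no
#' boundary correction is applied.
#'
#' @param fit_nested,fit_full `tdcm_fit` objects; the nested model must have
#'   strictly fewer free parameters.
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
lrt_tdcm <- function(fit_nested, fit_full) {
  stopifnot(inherits(fit_nested, "tdcm_fit"), inherits(fit_full, "tdcm_fit"))
  df <- fit_full$n_parameters - fit_nested$n_parameters
  if (df <= 0L)
    stop("models are not nested: the first argument must have fewer free ",
         "parameters than the second")
  if (fit_nested$n_obs != fit_full$n_obs)
    stop("fits are on different numbers of examinees")
  stat <- max(0, 2 * (fit_full$logLik - fit_nested$logLik))
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
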