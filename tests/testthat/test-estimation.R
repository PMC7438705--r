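# small generating models used throughout
tiny_model <- function(shape = "linear", n_items = 3, n_times = 3,
                       p_gain = 0.4) {
  h <- hierarchy_shape(shape, 3)
  q <- qmatrix(qvector_pool(3)[c(3, 6, 7, 1, 2)[seq_len(n_items)], ,
                               drop = FALSE]) # 100, 110, 111, 001, 010
  sp <- profile_space(h)
  tdcm_model(q, h, default_study_params(q, h),
             delta = rep(1 / sp$n_profiles, sp$n_profiles),
             tau = kernel_to_transitions(sp, p_gain),
             n_times = n_times)
}

sim_from_model <- function(model, N, seed) {
  set.seed(seed)
  C <- model$space$n_profiles
  Tt <- model$n_times
  traj <- matrix(0L, N, Tt)
  traj[, 1] <- sample.int(C, N, TRUE, prob = model$delta)
  if (Tt > 1) for (t in 2:Tt) for (r in seq_len(C)) {
    i <- which(traj[, t - 1] == r)
    if (length(i)) traj[i, t] <- sample.int(C, length(i), TRUE,
                                            prob = model$tau[[t - 1]][r, ])
  }
  y <- generate_responses(traj, model$item_params, model$space, seed + 1)
  list(truth = traj, responses = y)
}

test_that("forward log-likelihood equals exhaustive trajectory enumeration", {
  set.seed(15)
  for (case in list(list("linear", 3), list("divergent", 3),
                    list("independent", 2))) {
    m <- tiny_model(case[[1]], n_items = 3, n_times = case[[2]])
    sim <- sim_from_model(m, N = 5, seed = 101)
    p <- longdcm:::item_prob_matrix(m$item_params, m$space)
    want <- oracle_loglik(m$delta, m$tau, p, sim$responses)
    expect_equal(loglik_tdcm(m, sim$responses), want, tolerance = 1e-8)
  }
})

test_that("chain of length one reduces to a finite mixture", {
  m <- tiny_model("linear", n_items = 5, n_times = 1)
  sim <- sim_from_model(m, N = 20, seed = 3)
  p <- longdcm:::item_prob_matrix(m$item_params, m$space)
  mix <- 0
  for (n in 1:20) {
    y <- sim$responses[n, , 1]
    lik <- sum(m$delta * apply(p, 2, function(pc)
      prod(ifelse(y == 1, pc, 1 - pc))))
    mix <- mix + log(lik)
  }
  expect_equal(loglik_tdcm(m, sim$responses), mix, tolerance = 1e-10)
})

test_that("a degenerate prevalence gives the single-profile Bernoulli likelihood", {
  m <- tiny_model("linear", n_items = 4, n_times = 3)
  C <- m$space$n_profiles
  m$delta <- c(0, 0, 1, 0) # everyone starts (and stays) at profile 110
  m$tau <- rep(list(diag(C)), 2)
  sim <- sim_from_model(m, N = 15, seed = 12)
  p <- longdcm:::item_prob_matrix(m$item_params, m$space)[, 3]
  bern <- sum(dbinom(sim$responses, 1,
                     rep(rep(p, each = 15), 3), log = TRUE))
  expect_equal(loglik_tdcm(m, sim$responses), bern, tolerance = 1e-8)
})

test_that("posteriors are consistent and match the data-generating trajectory", {
  m <- tiny_model("linear", n_items = 3)
  sim <- sim_from_model(m, N = 30, seed = 7)
  ps <- e_step(m, sim$responses)
  expect_true(all(abs(apply(ps$gamma, c(1, 3), sum) - 1) < 1e-8))
  for (t in 1:2) {
    expect_true(all(abs(apply(ps$xi[[t]], 1, sum) - 1) < 1e-8))
    expect_lt(max(abs(apply(ps$xi[[t]], c(1, 3), sum) - ps$gamma[, , t + 1])),
              1e-8)
    expect_lt(max(abs(apply(ps$xi[[t]], c(1, 2), sum) - ps$gamma[, , t])),
              1e-8)
  }
  # near-deterministic items (all 7 q-vectors pin every profile apart)
  # concentrate the posterior on the generating trajectory
  q7 <- qmatrix(qvector_pool(3))
  sharp <- tdcm_model(q7, m$hierarchy,
                      lapply(default_study_params(q7, m$hierarchy),
                             function(ip) longdcm:::new_item_params(
                               -20, rep(40, length(ip$effects)), ip$subsets)),
                      m$delta, m$tau, 3)
  sims <- sim_from_model(sharp, N = 25, seed = 9)
  pss <- e_step(sharp, sims$responses)
  for (t in 1:3) {
    map <- max.col(pss$gamma[, , t], ties.method = "first")
    expect_equal(map, sims$truth[, t])
    expect_true(all(pss$gamma[cbind(1:25, map, t)] > 0.99))
  }
  # uninformative items: time-1 posterior equals the prior
  flat <- tiny_model("linear", n_items = 3)
  flat$item_params <- lapply(flat$item_params, function(ip)
    longdcm:::new_item_params(0, rep(0, length(ip$effects)), ip$subsets))
  flat$delta <- c(0.1, 0.2, 0.3, 0.4)
  psf <- e_step(flat, sim$responses)
  expect_equal(psf$gamma[1, , 1], flat$delta, tolerance = 1e-10)
})

test_that("M-step matches closed forms and an independent logistic solver", {
  m <- tiny_model("linear", n_items = 3)
  sim <- sim_from_model(m, N = 400, seed = 21)
  # posteriors concentrated at the truth: delta update = empirical frequencies
  C <- m$space$n_profiles
  gamma <- array(0, dim = c(400, C, 3))
  for (t in 1:3) gamma[cbind(1:400, sim$truth[, t], t)] <- 1
  xi <- lapply(1:2, function(t) {
    x <- array(0, dim = c(400, C, C))
    x[cbind(1:400, sim$truth[, t], sim$truth[, t + 1])] <- 1
    x
  })
  ps <- structure(list(gamma = gamma, xi = xi), class = "tdcm_posteriors")
  up <- m_step(ps, sim$responses, m, monotone = FALSE)
  expect_equal(up$delta, tabulate(sim$truth[, 1], C) / 400, tolerance = 1e-9)
  # item update agrees with glm on the complete-data expansion
  P <- m$space$profiles
  for (i in 1:3) {
    X <- longdcm:::item_design_matrix(m$item_params[[i]]$subsets, P)
    prof <- as.vector(sim$truth)
    y <- as.vector(sim$responses[, i, ])
    fit <- suppressWarnings(stats::glm(y ~ X[prof, -1, drop = FALSE],
                                       family = stats::binomial()))
    got <- c(up$item_params[[i]]$intercept, up$item_params[[i]]$effects)
    expect_equal(unname(got), unname(stats::coef(fit)), tolerance = 1e-4)
  }
  # masked transition cells stay exactly zero
  mf <- m
  mf$forbid_regression <- TRUE
  upf <- m_step(ps, sim$responses, mf, monotone = FALSE)
  supp <- longdcm:::transition_support(m$space)
  for (t in 1:2) expect_true(all(upf$tau[[t]][supp == 0] == 0))
  for (t in 1:2) expect_equal(unname(rowSums(upf$tau[[t]])), rep(1, C))
})

test_that("EM is deterministic, monotone in likelihood, and respects nesting", {
  sim <- make_small_sim("linear", "Q2", N = 150, seed = 55)
  ctl <- list(n_starts = 2, seed = 10, max_iter = 150)
  f1 <- fit_tdcm(sim$responses, sim$design$qmatrix, sim$hierarchy,
                 control = ctl)
  f2 <- fit_tdcm(sim$responses, sim$design$qmatrix, sim$hierarchy,
                 control = ctl)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-12)
  expect_true(all(diff(f1$trace) >= -1e-8))
  ft <- fit_tdcm(sim$responses, sim$design$qmatrix, sim$hierarchy,
                 variant = "tdcm", control = ctl)
  expect_true(all(diff(ft$trace) >= -1e-8))
  expect_lte(f1$logLik, ft$logLik + 1e-6)
  expect_lt(f1$n_parameters, ft$n_parameters)
  # likelihood-ratio test plumbing
  out <- lrt_tdcm(f1, ft)
  expect_gte(out$statistic, 0)
  expect_equal(out$df, ft$n_parameters - f1$n_parameters)
  expect_true(out$p_value >= 0 && out$p_value <= 1)
  expect_error(lrt_tdcm(ft, f1), "not nested")
})

test_that("MAP classification recovers noiseless data and breaks ties low", {
  h <- hierarchy_shape("linear", 3)
  q7 <- qmatrix(qvector_pool(3))
  sp <- profile_space(h)
  sharp <- tdcm_model(q7, h,
                      lapply(default_study_params(q7, h), function(ip)
                        longdcm:::new_item_params(-20, rep(40, length(ip$effects)),
                                                  ip$subsets)),
                      rep(0.25, 4), kernel_to_transitions(sp, 0.4), 3)
  sim <- sim_from_model(sharp, N = 40, seed = 2)
  cls <- classify_profiles(sharp, sim$responses)
  expect_equal(cls$profiles, sim$truth)
  expect_true(all(abs(apply(cls$posterior, c(1, 3), sum) - 1) < 1e-8))
  # uninformative data: everyone gets the prevalence argmax at time 1
  flat <- tdcm_model(q7, h,
                     lapply(default_study_params(q7, h), function(ip)
                       longdcm:::new_item_params(0, rep(0, length(ip$effects)),
                                                 ip$subsets)),
                     c(0.1, 0.5, 0.3, 0.1), kernel_to_transitions(sp, 0.4), 3)
  clsf <- classify_profiles(flat, sim$responses)
  expect_true(all(clsf$profiles[, 1] == 2L))
})

test_that("model container validates dimensions and missing data", {
  m <- tiny_model()
  sim <- sim_from_model(m, N = 5, seed = 1)
  bad <- sim$responses
  bad[1, 1, 1] <- NA
  expect_error(loglik_tdcm(m, bad), "missing|complete")
  expect_error(loglik_tdcm(m, sim$responses[, , 1:2]), "time points")
  expect_error(tdcm_model(m$qmatrix, m$hierarchy, m$item_params,
                          c(0.5, 0.5, 0, 0.2), m$tau, 3), "summing to 1")
})
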