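#' Profile and marginal correct classification rates
#'
#' `profile_ccr()` is the fraction of examinees whose estimated attribute
#' profile at a time point matches the true profile exactly;
#' `marginal_ccr()` is the fraction agreeing on a single attribute. The
#' profile rate can never exceed the smallest marginal rate at the same time
#' point.
#'
#' @param true_profiles,est_profiles N x T matrices of canonical profile
#'   indices (as returned by [sample_trajectories()] and
#'   [classify_profiles()]), or plain vectors for a single time point.
#' @param time Time point to score (ignored for vector input).
#' @return A rate in \[0, 1\].
#' @export
profile_ccr <- function(true_profiles, est_profiles, time = 1L) {
  tv <- col_or_vector(true_profiles, time)
  ev <- col_or_vector(est_profiles, time)
  if (length(tv) != length(ev)) stop("true and estimated lengths differ")
  mean(tv == ev)
}

#' @rdname profile_ccr
#' @param space The `profile_space` the indices refer to.
#' @param attribute Attribute index (1-based).
#' @export
marginal_ccr <- function(true_profiles, est_profiles, space, attribute,
                         time = 1L) {
  stopifnot(inherits(space, "profile_space"))
  tv <- col_or_vector(true_profiles, time)
  ev <- col_or_vector(est_profiles, time)
  if (length(tv) != length(ev)) stop("true and estimated lengths differ")
  mean(space$profiles[tv, attribute] == space$profiles[ev, attribute])
}

col_or_vector <- function(x, time) {
  if (is.matrix(x)) x[, time] else x
}

#' Run the Monte Carlo classification-accuracy study
#'
#' For every condition (attribute hierarchy crossed with Q-matrix design)
#' the runner repeats: simulate a data set under the study's generating
#' model, fit the matching model by EM (H-TDCM for hierarchical conditions,
#' TDCM for independent attributes), MAP-classify every examinee at every
#' time point, and score profile and marginal correct classification rates.
#' Rates are averaged over replications with Monte Carlo standard errors;
#' replication r of any condition uses seed `seed + r`, so the whole study
#' is reproducible from one integer and any condition can be re-run alone.
#'
#' @param hierarchies Character vector of hierarchy shapes (or a list of
#'   `attribute_hierarchy` objects).
#' @param designs Character vector of design ids among `"Q1"`, `"Q2"`,
#'   `"Q3"`.
#' @param n_reps Replications per condition.
#' @param seed Base seed.
#' @param n_items,n_examinees,n_times,p_gain Passed to [study_design()].
#' @param fit_control Control list passed to [fit_tdcm()] (the study default
#'   uses `n_starts = 3`).
#' @param verbose Print one line per replication.
#' @return An object of class `study_result`: a list with `rates` (a long
#'   data frame with columns `hierarchy`, `design`, `metric`
#'   (`"profile_ccr"`/`"marginal_ccr"`), `attribute` (NA for profile rates),
#'   `time`, `estimate` (mean over replications), `mc_se`), `summary` (per
#'   condition: grand mean profile CCR and mean marginal CCR with MC
#'   standard errors), `n_reps`, `seed`, `failures` (count of excluded
#'   replications per condition) and `settings`.
#' @export
run_study <- function(hierarchies = c("independent", "divergent", "linear"),
                      designs = c("Q1", "Q2", "Q3"),
                      n_reps = 100L, seed = 0L,
                      n_items = 10L, n_examinees = 1000L, n_times = 3L,
                      p_gain = 0.4, fit_control = list(), verbose = FALSE) {
  fit_control <- utils::modifyList(list(n_starts = 3L), fit_control)
  hlist <- lapply(hierarchies, function(h)
    if (is.character(h)) hierarchy_shape(h) else h)
  hnames <- vapply(hlist, function(h) h$label, character(1L))
  rates <- list()
  summary_rows <- list()
  failures <- list()
  for (hi in seq_along(hlist)) {
    hierarchy <- hlist[[hi]]
    variant <- if (nrow(hierarchy$edges) == 0L) "tdcm" else "htdcm"
    for (design in designs) {
      des <- study_design(hierarchy, design, n_items = n_items,
                          n_examinees = n_examinees, n_times = n_times,
                          p_gain = p_gain)
      K <- des$space$n_attributes
      prof_rep <- matrix(NA_real_, n_reps, n_times)
      marg_rep <- array(NA_real_, dim = c(n_reps, K, n_times))
      n_fail <- 0L
      for (r in seq_len(n_reps)) {
        seed_r <- seed + r
        res <- tryCatch({
          sim <- simulate_study(des, seed_r)
          ctl <- utils::modifyList(fit_control, list(seed = seed_r))
          fit <- fit_tdcm(sim$responses, des$qmatrix, hierarchy,
                          variant = variant, control = ctl)
          cls <- classify_profiles(fit, sim$responses)
          # TDCM fits index the full 2^K space; map truth into that space
          truth <- if (identical(fit$model$space$profiles,
                                 des$space$profiles)) sim$truth
                   else matrix(profile_index(
                          des$space$profiles[sim$truth, , drop = FALSE],
                          fit$model$space),
                        nrow(sim$truth), ncol(sim$truth))
          list(fit = fit, cls = cls, truth = truth,
               space = fit$model$space)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          n_fail <- n_fail + 1L
          warning(sprintf("replication %d of %s x %s failed: %s",
                          r, hnames[hi], design, conditionMessage(res)),
                  call. = FALSE)
          next
        }
        for (t in seq_len(n_times)) {
          prof_rep[r, t] <- profile_ccr(res$truth, res$cls$profiles, t)
          for (k in seq_len(K))
            marg_rep[r, k, t] <- marginal_ccr(res$truth, res$cls$profiles,
                                              res$space, k, t)
        }
        if (verbose)
          message(sprintf("%s x %s rep %d (seed %d): logLik %.1f, CCR(T) %s",
                          hnames[hi], design, r, seed_r, res$fit$logLik,
                          paste(sprintf("%.3f", prof_rep[r, ]),
                                collapse = "/")))
      }
      ok <- !is.na(prof_rep[, 1L])
      mc_se <- function(v) stats::sd(v) / sqrt(length(v))
      for (t in seq_len(n_times)) {
        rates[[length(rates) + 1L]] <- data.frame(
          hierarchy = hnames[hi], design = design, metric = "profile_ccr",
          attribute = NA_integer_, time = t,
          estimate = mean(prof_rep[ok, t]), mc_se = mc_se(prof_rep[ok, t]))
        for (k in seq_len(K))
          rates[[length(rates) + 1L]] <- data.frame(
            hierarchy = hnames[hi], design = design, metric = "marginal_ccr",
            attribute = k, time = t,
            estimate = mean(marg_rep[ok, k, t]),
            mc_se = mc_se(marg_rep[ok, k, t]))
      }
      grand <- rowMeans(prof_rep[ok, , drop = FALSE])
      marg_grand <- apply(marg_rep[ok, , , drop = FALSE], 1L, mean)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        hierarchy = hnames[hi], design = design,
        mean_profile_ccr = mean(grand), mc_se_profile = mc_se(grand),
        mean_marginal_ccr = mean(marg_grand), mc_se_marginal = mc_se(marg_grand),
        n_used = sum(ok))
      failures[[paste(hnames[hi], design, sep = ":")]] <- n_fail
    }
  }
  structure(list(rates = do.call(rbind, rates),
                 summary = do.call(rbind, summary_rows),
                 n_reps = n_reps, seed = seed,
                 failures = unlist(failures),
                 settings = list(n_items = n_items, n_examinees = n_examinees,
                                 n_times = n_times, p_gain = p_gain)),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("Monte Carlo classification study:", x$n_reps, "replications, N =",
      x$settings$n_examinees, ", I =", x$settings$n_items, ", T =",
      x$settings$n_times, "\n\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Tabulate a study result like a classification-rates report
#'
#' Reshapes a `study_result` into the wide layout conventional for
#' classification-accuracy tables: one column per condition (hierarchy x
#' design), rows for the profile CCR at each time point and its mean, then
#' the marginal CCR for each attribute at each time point with per-time
#' means.
#'
#' @param result A `study_result`.
#' @param digits Rounding for display; `NULL` keeps full precision.
#' @return A data frame with a `row` label column and one column per
#'   condition.
#' @export
study_table <- function(result, digits = 3L) {
  stopifnot(inherits(result, "study_result"))
  r <- result$rates
  conds <- unique(r[, c("hierarchy", "design")])
  Tt <- result$settings$n_times
  K <- max(r$attribute, na.rm = TRUE)
  labels <- c(paste0("profile_ccr_t", seq_len(Tt)), "profile_ccr_mean")
  for (t in seq_len(Tt))
    labels <- c(labels, paste0("marginal_ccr_t", t, "_a", seq_len(K)),
                paste0("marginal_ccr_t", t, "_mean"))
  out <- data.frame(row = labels)
  for (j in seq_len(nrow(conds))) {
    sub <- r[r$hierarchy == conds$hierarchy[j] & r$design == conds$design[j], ]
    prof <- sub[sub$metric == "profile_ccr", ]
    prof <- prof[order(prof$time), ]
    col <- c(prof$estimate, mean(prof$estimate))
    for (t in seq_len(Tt)) {
      m <- sub[sub$metric == "marginal_ccr" & sub$time == t, ]
      m <- m[order(m$attribute), ]
      col <- c(col, m$estimate, mean(m$estimate))
    }
    if (!is.null(digits)) col <- round(col, digits)
    out[[paste(conds$hierarchy[j], conds$design[j], sep = ".")]] <- col
  }
  out
}
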