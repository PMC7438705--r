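#' Read and write longitudinal response data (long CSV)
#'
#' The long layout has one row per examinee x time x item with columns
#' `examinee,time,item,response` (1-based indices, binary response).
#' `read_responses_long()` builds the N x I x T array used by the fitting
#' functions; missing cells are an error (complete data are required).
#'
#' @param path CSV file path.
#' @return `read_responses_long()` returns an N x I x T binary array.
#' @export
read_responses_long <- function(path) {
  d <- utils::read.csv(path)
  need <- c("examinee", "time", "item", "response")
  if (!all(need %in% names(d)))
    stop("long response CSV needs columns ", paste(need, collapse = ", "))
  ex <- sort(unique(d$examinee))
  N <- length(ex); I <- max(d$item); Tt <- max(d$time)
  y <- array(NA_integer_, dim = c(N, I, Tt))
  y[cbind(match(d$examinee, ex), d$item, d$time)] <- d$response
  if (anyNA(y)) stop("incomplete response data: every examinee needs a ",
                     "response for every item at every time point")
  check_responses(y)
}

#' @rdname read_responses_long
#' @param responses N x I x T binary array.
#' @export
write_responses_long <- function(responses, path) {
  check_responses(responses)
  d <- dim(responses)
  g <- expand.grid(examinee = seq_len(d[1L]), item = seq_len(d[2L]),
                   time = seq_len(d[3L]))
  out <- data.frame(examinee = g$examinee, time = g$time, item = g$item,
                    response = responses[cbind(g$examinee, g$item, g$time)])
  out <- out[order(out$examinee, out$time, out$item), ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write true trajectories to CSV
#'
#' Columns `examinee,time,profile_index,alpha1..alphaK`; profile indices are
#' 1-based into the canonical profile space.
#'
#' @param trajectories N x T profile-index matrix.
#' @param space The `profile_space` the indices refer to.
#' @param path Output CSV path.
#' @export
write_truth_csv <- function(trajectories, space, path) {
  stopifnot(inherits(space, "profile_space"))
  N <- nrow(trajectories); Tt <- ncol(trajectories)
  g <- expand.grid(examinee = seq_len(N), time = seq_len(Tt))
  idx <- trajectories[cbind(g$examinee, g$time)]
  out <- cbind(data.frame(examinee = g$examinee, time = g$time,
                          profile_index = idx),
               as.data.frame(space$profiles[idx, , drop = FALSE],
                             row.names = FALSE))
  names(out)[-(1:3)] <- paste0("alpha", seq_len(space$n_attributes))
  out <- out[order(out$examinee, out$time), ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an attribute hierarchy from a YAML or JSON config
#'
#' Accepts either a named shape (`attributes: 3`, `shape: linear`) or an
#' explicit edge list (`attributes: 3`, `edges: [[1,2],[2,3]]`). The format
#' is chosen by file extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path Config file path.
#' @return An `attribute_hierarchy`.
#' @export
read_hierarchy_config <- function(path) {
  cfg <- read_config(path)
  K <- cfg$attributes %||% stop("config needs an 'attributes' field")
  if (!is.null(cfg$shape)) return(hierarchy_shape(cfg$shape, K))
  attribute_hierarchy(K, cfg$edges)
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Serialize a fitted model (or model) to JSON and back
#'
#' All parameter blocks are written: per-item intercepts and free effects
#' (keyed by comma-joined 1-based attribute subsets), the initial
#' prevalence, the transition matrices, the Q-matrix, hierarchy edges,
#' variant and options. `read_model_json()` reconstructs a `tdcm_model`.
#'
#' @param model A `tdcm_model` or `tdcm_fit`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  fit <- NULL
  if (inherits(model, "tdcm_fit")) {
    fit <- model
    model <- model$model
  }
  stopifnot(inherits(model, "tdcm_model"))
  obj <- list(
    variant = model$variant,
    n_times = model$n_times,
    forbid_regression = model$forbid_regression,
    hierarchy = list(attributes = model$hierarchy$n_attributes,
                     edges = model$hierarchy$edges,
                     label = model$hierarchy$label),
    qmatrix = model$qmatrix$entries,
    items = lapply(model$item_params, function(ip)
      list(intercept = ip$intercept, effects = as.list(ip$effects))),
    delta = model$delta,
    tau = model$tau)
  if (!is.null(fit))
    obj <- c(obj, list(logLik = fit$logLik, converged = fit$converged,
                       n_parameters = fit$n_parameters, AIC = fit$AIC,
                       BIC = fit$BIC, seed = fit$seed,
                       n_starts = fit$n_starts))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  hierarchy <- attribute_hierarchy(obj$hierarchy$attributes,
                                   obj$hierarchy$edges,
                                   label = obj$hierarchy$label)
  q <- qmatrix(obj$qmatrix)
  items <- lapply(obj$items, function(it) {
    subsets <- lapply(names(it$effects), function(k)
      as.integer(strsplit(k, ",")[[1L]]))
    new_item_params(it$intercept, unlist(it$effects) %||% numeric(0), subsets)
  })
  tau <- obj$tau
  if (is.array(tau) && length(dim(tau)) == 3L)
    tau <- lapply(seq_len(dim(tau)[1L]), function(i) tau[i, , ])
  tdcm_model(q, hierarchy, items, obj$delta, tau, obj$n_times,
             variant = obj$variant,
             forbid_regression = isTRUE(obj$forbid_regression))
}
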