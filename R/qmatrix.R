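#' Canonical list of nonzero q-vectors
#'
#' All 2^K - 1 nonzero binary K-vectors (candidate item q-vectors under the
#' unstructured Q-matrix approach), in the canonical order used throughout the
#' package: ascending number of measured attributes, ties broken by the vector
#' read as a binary number with attribute 1 as the most significant bit.
#'
#' @param n_attributes Number of attributes K.
#' @return A (2^K - 1) x K binary integer matrix.
#' @export
qvector_pool <- function(n_attributes) {
  K <- as.integer(n_attributes)
  v <- as.matrix(expand.grid(rep(list(0:1), K))[, K:1, drop = FALSE])
  v <- v[rowSums(v) > 0L, , drop = FALSE]
  v <- v[order(rowSums(v), profile_binary_value(v)), , drop = FALSE]
  storage.mode(v) <- "integer"
  colnames(v) <- paste0("A", seq_len(K))
  rownames(v) <- apply(v, 1L, paste, collapse = "")
  v
}

new_qmatrix <- function(entries, item_labels = NULL) {
  entries <- as.matrix(entries)
  storage.mode(entries) <- "integer"
  if (any(!entries %in% c(0L, 1L))) stop("Q-matrix entries must be binary")
  if (any(rowSums(entries) == 0L))
    stop("Q-matrix has an all-zero row: every item must measure >= 1 attribute")
  if (any(colSums(entries) == 0L))
    warning("Q-matrix has an all-zero column: an attribute is never measured",
            call. = FALSE)
  colnames(entries) <- paste0("A", seq_len(ncol(entries)))
  rownames(entries) <- item_labels %||% paste0("item", seq_len(nrow(entries)))
  structure(list(entries = entries), class = "qmatrix")
}

#' Construct a Q-matrix
#'
#' Validates and wraps an items x attributes binary incidence matrix. Row i,
#' column k is 1 iff item i measures attribute k. Every item must measure at
#' least one attribute and every attribute must be measured by at least one
#' item (attributes measured by fewer than three items are flagged by
#' [coverage_report()], not rejected here).
#'
#' @param entries I x K binary matrix (rows = items, columns = attributes).
#' @param item_labels Optional character vector of item names.
#' @return An object of class `qmatrix`.
#' @seealso [build_design()], [coverage_report()], [read_qmatrix()]
#' @export
qmatrix <- function(entries, item_labels = NULL) new_qmatrix(entries, item_labels)

#' @export
print.qmatrix <- function(x, ...) {
  cat("Q-matrix:", nrow(x$entries), "items x", ncol(x$entries), "attributes\n")
  print(x$entries)
  invisible(x)
}

# disjoint R^T-block count: each block consumes one copy of every row of R^T,
# so the maximum is min over distinct R^T rows of floor(#copies in Q / #copies
# needed). This closed form is exact (blocks are multisets of rows).
rt_block_count <- function(q_entries, rt_rows) {
  key_q <- apply(q_entries, 1L, paste, collapse = "")
  key_r <- apply(rt_rows, 1L, paste, collapse = "")
  need <- table(key_r)
  have <- table(factor(key_q, levels = names(need)))
  min(floor(have / need))
}

#' Count disjoint R-transpose blocks in a Q-matrix
#'
#' Counts the maximum number of disjoint row-subsets of the Q-matrix that each
#' equal, up to row permutation, the rows of the transposed reachability
#' matrix. For independent attributes the R-matrix is the identity, so this
#' coincides with counting disjoint identity blocks.
#'
#' @param q A `qmatrix`.
#' @param r A K x K reachability matrix, as from [reachability_matrix()].
#' @return Integer block count.
#' @export
count_rt_blocks <- function(q, r) {
  stopifnot(inherits(q, "qmatrix"))
  if (ncol(q$entries) != ncol(r)) stop("Q-matrix and R-matrix disagree on K")
  rt_block_count(q$entries, t(r))
}

#' Canonical Q-matrix designs Q1, Q2, Q3
#'
#' Builds the three deterministic Q-matrix designs contrasted in the
#' classification-accuracy study, for any attribute hierarchy:
#' \describe{
#'   \item{Q1}{contains no copy of the transposed reachability matrix R^T
#'     (and, for independent attributes, never measures attribute 1 in
#'     isolation);}
#'   \item{Q2}{contains exactly one R^T block, plus one identity block when
#'     the identity differs from R^T (i.e. for a non-trivial hierarchy);}
#'   \item{Q3}{contains exactly two R^T blocks.}
#' }
#' Remaining rows are filled by cycling through the canonical q-vector pool
#' ([qvector_pool()]), skipping any q-vector whose inclusion would change the
#' design's defining R^T-block count (or, for Q1 under independent attributes,
#' would measure attribute 1 in isolation). The construction is fully
#' deterministic: identical inputs give a bit-identical matrix.
#'
#' @param hierarchy An `attribute_hierarchy`.
#' @param design_id One of `"Q1"`, `"Q2"`, `"Q3"`.
#' @param n_items Number of items I (rows); must accommodate the design's
#'   mandatory blocks.
#' @return A `qmatrix` with `n_items` rows.
#' @examples
#' build_design(hierarchy_shape("linear", 3), "Q2", 10)
#' @export
build_design <- function(hierarchy, design_id = c("Q1", "Q2", "Q3"),
                         n_items = 10L) {
  stopifnot(inherits(hierarchy, "attribute_hierarchy"))
  design_id <- match.arg(design_id)
  n_items <- as.integer(n_items)
  K <- hierarchy$n_attributes
  R <- reachability_matrix(hierarchy)
  rt <- t(R)
  id <- diag(1L, K)
  target <- c(Q1 = 0L, Q2 = 1L, Q3 = 2L)[[design_id]]
  independent <- nrow(hierarchy$edges) == 0L

  blocks <- switch(design_id,
    Q1 = matrix(integer(0), ncol = K),
    Q2 = if (identical(unname(rt), unname(id))) rt else rbind(rt, id),
    Q3 = rbind(rt, rt))
  if (n_items < nrow(blocks))
    stop("n_items = ", n_items, " is too small for design ", design_id,
         " (needs >= ", nrow(blocks), " rows)")

  pool <- qvector_pool(K)
  rows <- blocks
  i <- 0L
  skipped_all <- 0L
  while (nrow(rows) < n_items) {
    i <- i %% nrow(pool) + 1L
    cand <- pool[i, , drop = FALSE]
    trial <- rbind(rows, cand)
    ok <- rt_block_count(trial, rt) == target
    if (ok && design_id == "Q1" && independent)
      ok <- !(sum(cand) == 1L && cand[1L, 1L] == 1L)
    if (ok) {
      rows <- trial
      skipped_all <- 0L
    } else {
      skipped_all <- skipped_all + 1L
      if (skipped_all >= nrow(pool))
        stop("cannot fill design ", design_id, ": every q-vector violates it")
    }
  }
  dimnames(rows) <- NULL
  new_qmatrix(rows)
}

#' Gamma matrix of a Q-matrix over a profile space
#'
#' The Gamma matrix is the items x profiles indicator of which attribute
#' profiles attain an item's maximal correct-response probability. Under a
#' monotone measurement model that is exactly the set of profiles mastering
#' every attribute the item measures, so entry (i, c) = 1 iff profile c
#' dominates q-vector i componentwise.
#'
#' @param q A `qmatrix`.
#' @param space A `profile_space`.
#' @return An I x C binary matrix of class `gamma_matrix` (rows = items,
#'   columns = profiles, labelled by profile string).
#' @export
gamma_matrix <- function(q, space) {
  stopifnot(inherits(q, "qmatrix"), inherits(space, "profile_space"))
  if (ncol(q$entries) != space$n_attributes)
    stop("Q-matrix and profile space disagree on K")
  Q <- q$entries
  P <- space$profiles
  g <- matrix(0L, nrow(Q), nrow(P),
              dimnames = list(rownames(Q), rownames(P)))
  for (i in seq_len(nrow(Q)))
    g[i, ] <- as.integer(P %*% Q[i, ] == sum(Q[i, ]))
  class(g) <- c("gamma_matrix", class(g))
  g
}

#' Separability of a Gamma matrix
#'
#' A Gamma matrix is separable iff all its profile columns are pairwise
#' distinct; separability is a necessary condition for strict identification
#' of saturated diagnostic models.
#'
#' @param g A `gamma_matrix` (or any binary items x profiles matrix).
#' @return `TRUE` iff no two columns coincide.
#' @export
is_separable <- function(g) {
  !any(duplicated(apply(g, 2L, paste, collapse = "")))
}

#' Attribute coverage report for a Q-matrix
#'
#' Counts how many items measure each attribute and flags attributes measured
#' by fewer than three items, the rule-of-thumb minimum tied to
#' identifiability results for diagnostic models.
#'
#' @param q A `qmatrix`.
#' @return A list with `counts` (named integer vector, one entry per
#'   attribute) and `warnings` (character vector, one message per attribute
#'   with fewer than three items; empty when all counts are >= 3).
#' @export
coverage_report <- function(q) {
  stopifnot(inherits(q, "qmatrix"))
  counts <- colSums(q$entries)
  low <- counts < 3L
  warnings <- if (any(low))
    sprintf("attribute %s is measured by only %d item%s (< 3)",
            names(counts)[low], counts[low], ifelse(counts[low] == 1L, "", "s"))
  else character(0)
  list(counts = counts, warnings = warnings)
}

#' Read / write a Q-matrix CSV
#'
#' The CSV layout has a header `item,A1,...,AK`, one row per item, binary
#' cells; the first column holds item labels.
#'
#' @param path File path.
#' @return `read_qmatrix()` returns a `qmatrix`.
#' @export
read_qmatrix <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  new_qmatrix(as.matrix(d[, -1L, drop = FALSE]), item_labels = as.character(d[[1L]]))
}

#' @rdname read_qmatrix
#' @param q A `qmatrix` to write.
#' @export
write_qmatrix <- function(q, path) {
  stopifnot(inherits(q, "qmatrix"))
  d <- data.frame(item = rownames(q$entries), q$entries,
                  check.names = FALSE, row.names = NULL)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
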