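#' Attribute prerequisite hierarchies
#'
#' An attribute hierarchy is a directed acyclic graph on K binary latent
#' attributes in which an edge j -> k means "attribute j is a direct
#' prerequisite of attribute k". The hierarchy determines which attribute
#' profiles (binary K-vectors of masteries) are permissible: a profile may
#' master an attribute only if it masters all of its (direct and indirect)
#' prerequisites.
#'
#' Attributes are 1-indexed everywhere in the user-facing interface.
#'
#' @param n_attributes Number of attributes K (positive integer).
#' @param edges Prerequisite edges, as a two-column matrix (or a list of
#'   length-2 vectors) of 1-based attribute indices; row `c(j, k)` declares j a
#'   direct prerequisite of k. `NULL` or an empty matrix means no prerequisites
#'   (independent attributes).
#' @param label Optional free-text tag; defaults to `"independent"` when the
#'   edge set is empty and `"custom"` otherwise.
#'
#' @return An object of class `attribute_hierarchy` with elements
#'   `n_attributes`, `edges` (two-column integer matrix) and `label`.
#'
#' @examples
#' attribute_hierarchy(3, list(c(1, 2), c(2, 3)))        # linear chain
#' attribute_hierarchy(3)                                 # independent
#' hierarchy_shape("divergent", 3)                        # named shape
#' @seealso [hierarchy_shape()], [reachability_matrix()], [profile_space()]
#' @export
attribute_hierarchy <- function(n_attributes, edges = NULL, label = NULL) {
  K <- as.integer(n_attributes)
  if (length(K) != 1L || is.na(K) || K < 1L)
    stop("n_attributes must be a single positive integer")
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L) ||
      length(edges) == 0L) {
    E <- matrix(integer(0), ncol = 2L)
  } else {
    if (is.list(edges)) E <- do.call(rbind, lapply(edges, as.integer))
    else E <- matrix(as.integer(edges), ncol = 2L)
    if (ncol(E) != 2L) stop("edges must have two columns (from, to)")
    if (any(is.na(E)) || any(E < 1L) || any(E > K))
      stop("edge endpoints must be attribute indices in 1..", K)
    if (any(E[, 1L] == E[, 2L])) stop("self-edges are not allowed")
    E <- unique(E)
  }
  h <- structure(
    list(n_attributes = K, edges = E,
         label = label %||% if (nrow(E) == 0L) "independent" else "custom"),
    class = "attribute_hierarchy")
  cyc <- find_cycle(h)
  if (!is.null(cyc))
    stop("hierarchy is cyclic: ", paste(cyc, collapse = " -> "))
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct one of the three named three-way hierarchy shapes
#'
#' Convenience constructor for the shapes commonly contrasted in diagnostic
#' modelling: `independent` (no edges), `linear` (a single chain
#' 1 -> 2 -> ... -> K) and `divergent` (attribute 1 a direct prerequisite of
#' every other attribute).
#'
#' @param shape One of `"independent"`, `"linear"`, `"divergent"`.
#' @param n_attributes Number of attributes K.
#' @return An `attribute_hierarchy`.
#' @export
hierarchy_shape <- function(shape = c("independent", "linear", "divergent"),
                            n_attributes = 3L) {
  shape <- match.arg(shape)
  K <- as.integer(n_attributes)
  edges <- switch(shape,
    independent = NULL,
    linear = if (K > 1L) cbind(seq_len(K - 1L), 2:K) else NULL,
    divergent = if (K > 1L) cbind(rep(1L, K - 1L), 2:K) else NULL)
  attribute_hierarchy(K, edges, label = shape)
}

# Depth-first cycle detection; returns a cycle (vertex sequence) or NULL.
find_cycle <- function(hierarchy) {
  K <- hierarchy$n_attributes
  E <- hierarchy$edges
  if (nrow(E) == 0L) return(NULL)
  adj <- split(E[, 2L], factor(E[, 1L], levels = seq_len(K)))
  state <- integer(K) # 0 unvisited, 1 on stack, 2 done
  path <- integer(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    state[v] <<- 1L
    path <<- c(path, v)
    for (w in adj[[v]]) {
      if (state[w] == 1L) {
        i <- match(w, path)
        found <<- c(path[i:length(path)], w)
        return()
      }
      if (state[w] == 0L) visit(w)
      if (!is.null(found)) return()
    }
    state[v] <<- 2L
    path <<- path[-length(path)]
  }
  for (v in seq_len(K)) if (state[v] == 0L) visit(v)
  found
}

#' @export
print.attribute_hierarchy <- function(x, ...) {
  cat("Attribute hierarchy (", x$label, "): K = ", x$n_attributes, sep = "")
  if (nrow(x$edges) == 0L) cat(", no prerequisite edges\n")
  else cat(", edges: ",
           paste(x$edges[, 1L], x$edges[, 2L], sep = "->", collapse = ", "),
           "\n", sep = "")
  invisible(x)
}

#' Reachability (R-) matrix of a hierarchy
#'
#' The reachability matrix captures direct and indirect prerequisite
#' relations: entry (j, k) is 1 iff attribute j is a direct or indirect
#' prerequisite of attribute k, or j = k. It is the reflexive transitive
#' closure of the edge relation. Its transpose's rows are the "restricted"
#' q-vectors of the hierarchy.
#'
#' @param hierarchy An `attribute_hierarchy`.
#' @return A K x K binary integer matrix with unit diagonal.
#' @examples
#' reachability_matrix(hierarchy_shape("linear", 3))
#' @export
reachability_matrix <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "attribute_hierarchy"))
  K <- hierarchy$n_attributes
  R <- diag(1L, K)
  E <- hierarchy$edges
  if (nrow(E) > 0L) R[E] <- 1L
  # Warshall closure
  for (m in seq_len(K))
    R <- (R | (outer(R[, m], R[m, ]) > 0)) * 1L
  storage.mode(R) <- "integer"
  dimnames(R) <- list(paste0("A", seq_len(K)), paste0("A", seq_len(K)))
  R
}

#' Enumerate the permissible attribute-profile space
#'
#' Lists every binary K-vector consistent with the hierarchy (mastering an
#' attribute requires mastery of all its prerequisites), in the canonical
#' order: ascending mastery count, ties broken by the profile read as a binary
#' number with attribute 1 as the most significant bit. The all-zero profile
#' is always first and the all-one profile last. For K independent attributes
#' the space has 2^K profiles; for a single linear chain it has K + 1.
#'
#' @param hierarchy An `attribute_hierarchy`.
#' @return An object of class `profile_space`: a list with `profiles`
#'   (C x K binary matrix, rows in canonical order), `n_profiles`,
#'   `n_attributes` and the generating `hierarchy`.
#' @examples
#' profile_space(hierarchy_shape("linear", 3))$profiles    # 000,100,110,111
#' @export
profile_space <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "attribute_hierarchy"))
  K <- hierarchy$n_attributes
  R <- reachability_matrix(hierarchy)
  all_prof <- as.matrix(expand.grid(rep(list(0:1), K))[, K:1, drop = FALSE])
  colnames(all_prof) <- paste0("A", seq_len(K))
  ok <- apply(all_prof, 1L, function(a) profile_consistent(a, R))
  prof <- all_prof[ok, , drop = FALSE]
  prof <- prof[order(rowSums(prof), profile_binary_value(prof)), , drop = FALSE]
  rownames(prof) <- apply(prof, 1L, paste, collapse = "")
  structure(list(profiles = prof, n_profiles = nrow(prof),
                 n_attributes = K, hierarchy = hierarchy),
            class = "profile_space")
}

# profile value as binary number, attribute 1 = most significant bit
profile_binary_value <- function(profiles) {
  K <- ncol(profiles)
  as.vector(profiles %*% 2^((K - 1L):0))
}

profile_consistent <- function(alpha, R) {
  K <- length(alpha)
  for (k in seq_len(K)) {
    if (alpha[k] == 1) {
      pre <- which(R[, k] == 1L)
      if (any(alpha[pre] == 0)) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.profile_space <- function(x, ...) {
  cat("Permissible profile space: C =", x$n_profiles, "profiles on",
      x$n_attributes, "attributes\n")
  print(x$profiles)
  invisible(x)
}

#' Test whether a profile is permissible under a hierarchy
#'
#' @param profile Binary vector of length K.
#' @param hierarchy An `attribute_hierarchy`.
#' @return `TRUE` iff the profile masters all prerequisites of each mastered
#'   attribute.
#' @export
is_permissible <- function(profile, hierarchy) {
  stopifnot(inherits(hierarchy, "attribute_hierarchy"))
  if (length(profile) != hierarchy$n_attributes)
    stop("profile length ", length(profile), " does not match K = ",
         hierarchy$n_attributes)
  if (!all(profile %in% c(0, 1))) stop("profile must be binary")
  profile_consistent(as.integer(profile), reachability_matrix(hierarchy))
}

# canonical index (1-based) of each row of `profiles` within a profile_space
profile_index <- function(profiles, space) {
  key <- apply(space$profiles, 1L, paste, collapse = "")
  idx <- match(apply(profiles, 1L, paste, collapse = ""), key)
  if (anyNA(idx)) stop("profile not in the permissible space")
  idx
}
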