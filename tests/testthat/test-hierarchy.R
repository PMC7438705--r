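test_that("reachability matrix captures direct and indirect prerequisites", {
  lin <- reachability_matrix(hierarchy_shape("linear", 3))
  # columns read as q-vectors are 100, 110, 111
  expect_equal(unname(lin), rbind(c(1, 1, 1), c(0, 1, 1), c(0, 0, 1)))
  expect_equal(unname(reachability_matrix(hierarchy_shape("independent", 3))),
               diag(1L, 3))
  div <- hierarchy_shape("divergent", 3)
  expect_equal(unname(reachability_matrix(div)),
               oracle_closure(3, list(c(1, 2), c(1, 3))))
})

test_that("reachability agrees with boolean-power closure on random DAGs", {
  set.seed(11)
  for (rep in 1:20) {
    K <- sample(2:6, 1)
    edges <- random_dag(K)
    h <- attribute_hierarchy(K, edges)
    expect_equal(unname(reachability_matrix(h)), oracle_closure(K, edges))
  }
})

test_that("reachability is idempotent under repeated closure", {
  set.seed(3)
  for (rep in 1:10) {
    K <- sample(2:6, 1)
    h <- attribute_hierarchy(K, random_dag(K))
    R <- reachability_matrix(h)
    R2 <- ((R %*% R) > 0) * 1L
    expect_equal(unname(R2), unname(R))
  }
})

test_that("cyclic edge sets are rejected with a cycle in the message", {
  expect_error(attribute_hierarchy(3, list(c(1, 2), c(2, 3), c(3, 1))),
               "cyclic")
  expect_error(attribute_hierarchy(2, list(c(1, 1))), "self-edges")
  expect_error(attribute_hierarchy(2, list(c(1, 5))), "endpoints")
})

test_that("permissible profile spaces match the three canonical hierarchies", {
  lin <- profile_space(hierarchy_shape("linear", 3))
  expect_equal(unname(lin$profiles),
               rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)))
  div <- profile_space(hierarchy_shape("divergent", 3))
  expect_equal(unname(div$profiles),
               rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(1, 1, 0),
                     c(1, 1, 1)))
  ind <- profile_space(hierarchy_shape("independent", 3))
  expect_equal(ind$n_profiles, 8L)
  expect_equal(c(ind$n_profiles, div$n_profiles, lin$n_profiles), c(8L, 5L, 4L))
})

test_that("profile enumeration equals brute-force filtering on random DAGs", {
  set.seed(7)
  for (rep in 1:20) {
    K <- sample(2:6, 1)
    edges <- random_dag(K)
    got <- profile_space(attribute_hierarchy(K, edges))$profiles
    want <- oracle_permissible(K, edges)
    sort_rows <- function(m) m[order(apply(m, 1, paste, collapse = "")), ,
                               drop = FALSE]
    expect_equal(unname(sort_rows(got)), unname(sort_rows(want)))
    # all-zero and all-one always present
    expect_true(any(rowSums(got) == 0) && any(rowSums(got) == K))
  }
})

test_that("a single chain on all K attributes gives exactly K + 1 profiles", {
  for (K in 2:6)
    expect_equal(profile_space(hierarchy_shape("linear", K))$n_profiles, K + 1L)
  # a partial chain is not a full chain: more profiles
  h <- attribute_hierarchy(4, list(c(1, 2), c(2, 3)))
  expect_gt(profile_space(h)$n_profiles, 5L)
})

test_that("canonical ordering is mastery count, then binary value", {
  sp <- profile_space(hierarchy_shape("independent", 3))
  expect_equal(rownames(sp$profiles),
               c("000", "001", "010", "100", "011", "101", "110", "111"))
})

test_that("is_permissible matches enumeration and validates input", {
  lin <- hierarchy_shape("linear", 3)
  div <- hierarchy_shape("divergent", 3)
  expect_false(is_permissible(c(0, 1, 0), lin))
  expect_true(is_permissible(c(1, 1, 1), lin))
  expect_false(is_permissible(c(0, 1, 1), div))
  expect_error(is_permissible(c(1, 0), lin), "length")
  set.seed(19)
  for (rep in 1:10) {
    K <- sample(2:5, 1)
    h <- attribute_hierarchy(K, random_dag(K))
    sp <- profile_space(h)
    keys <- rownames(sp$profiles)
    all_p <- oracle_all_profiles(K)
    for (i in seq_len(nrow(all_p)))
      expect_equal(is_permissible(all_p[i, ], h),
                   paste(all_p[i, ], collapse = "") %in% keys)
  }
})
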