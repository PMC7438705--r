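rt_of <- function(shape) t(reachability_matrix(hierarchy_shape(shape, 3)))

test_that("canonical designs satisfy their defining block structure", {
  for (shape in c("independent", "divergent", "linear")) {
    h <- hierarchy_shape(shape, 3)
    R <- reachability_matrix(h)
    expect_equal(count_rt_blocks(build_design(h, "Q1", 10), R), 0L)
    expect_equal(count_rt_blocks(build_design(h, "Q2", 10), R), 1L)
    expect_equal(count_rt_blocks(build_design(h, "Q3", 10), R), 2L)
    for (id in c("Q1", "Q2", "Q3")) {
      q <- build_design(h, id, 10)
      expect_equal(nrow(q$entries), 10L)
      expect_true(all(rowSums(q$entries) >= 1))
      # deterministic: bit-identical rebuild
      expect_identical(q$entries, build_design(h, id, 10)$entries)
    }
  }
})

test_that("linear Q2 stacks one R-transpose and one identity block", {
  q <- build_design(hierarchy_shape("linear", 3), "Q2", 10)
  rows <- apply(q$entries, 1, paste, collapse = "")
  expect_true(all(c("100", "110", "111") %in% rows))
  expect_true(all(c("100", "010", "001") %in% rows))
})

test_that("independent Q3 contains two identity blocks and Q1 never isolates attribute 1", {
  h <- hierarchy_shape("independent", 3)
  q3 <- build_design(h, "Q3", 10)
  keys <- apply(q3$entries, 1, paste, collapse = "")
  expect_true(all(table(factor(keys, levels = c("100", "010", "001"))) >= 2))
  q1 <- build_design(h, "Q1", 10)
  expect_false("100" %in% apply(q1$entries, 1, paste, collapse = ""))
})

test_that("build_design rejects too-small item budgets", {
  expect_error(build_design(hierarchy_shape("linear", 3), "Q3", 5),
               "too small")
})

test_that("gamma matrix encodes componentwise dominance of q-vectors", {
  lin <- profile_space(hierarchy_shape("linear", 3))
  g <- gamma_matrix(qmatrix(rt_of("linear")), lin)
  # row-by-row check of R^T over the linear space
  expect_equal(unname(unclass(g)),
               rbind(c(0, 1, 1, 1), c(0, 0, 1, 1), c(0, 0, 0, 1)))
  # full-mastery column is 1 for every item; empty profile column all zero
  q <- build_design(hierarchy_shape("linear", 3), "Q2", 10)
  g2 <- gamma_matrix(q, lin)
  expect_true(all(g2[, "111"] == 1))
  expect_true(all(g2[, "000"] == 0))
})

test_that("separability detects collapsed profile columns", {
  lin <- profile_space(hierarchy_shape("linear", 3))
  expect_true(is_separable(gamma_matrix(qmatrix(rt_of("linear")), lin)))
  # a single item 100 cannot tell 110 from 111
  q100 <- suppressWarnings(qmatrix(rbind(c(1, 0, 0))))
  expect_false(is_separable(gamma_matrix(q100, lin)))
  for (shape in c("independent", "divergent", "linear")) {
    h <- hierarchy_shape(shape, 3)
    two_rt <- qmatrix(rbind(t(reachability_matrix(h)),
                            t(reachability_matrix(h))))
    expect_true(is_separable(gamma_matrix(two_rt, profile_space(h))))
  }
})

test_that("one R-transpose block implies a separable gamma matrix", {
  set.seed(5)
  for (rep in 1:20) {
    K <- sample(2:4, 1)
    h <- attribute_hierarchy(K, random_dag(K))
    sp <- profile_space(h)
    extra <- qvector_pool(K)[sample(2^K - 1, 3, replace = TRUE), , drop = FALSE]
    q <- qmatrix(rbind(t(reachability_matrix(h)), extra))
    expect_gte(count_rt_blocks(q, reachability_matrix(h)), 1L)
    expect_true(is_separable(gamma_matrix(q, sp)))
  }
})

test_that("block counting handles stacks, designs and identity cycling", {
  lin <- hierarchy_shape("linear", 3)
  R <- reachability_matrix(lin)
  stacked <- qmatrix(rbind(t(R), t(R)))
  expect_equal(count_rt_blocks(stacked, R), 2L)
  # 10 items cycling the three single-attribute q-vectors: R^T = identity
  # under independence, so three full blocks fit
  ind <- hierarchy_shape("independent", 3)
  cyc <- qmatrix(diag(3)[rep(1:3, length.out = 10), ])
  expect_equal(count_rt_blocks(cyc, reachability_matrix(ind)), 3L)
})

test_that("coverage report counts items per attribute and warns below three", {
  q3 <- build_design(hierarchy_shape("linear", 3), "Q3", 10)
  cov3 <- coverage_report(q3)
  expect_true(all(cov3$counts >= 3))
  expect_length(cov3$warnings, 0)
  single <- coverage_report(qmatrix(diag(3)))
  expect_equal(unname(single$counts), c(1, 1, 1))
  expect_length(single$warnings, 3)
  # empty warning list iff min column sum >= 3
  expect_equal(length(coverage_report(qmatrix(diag(3)[rep(1:3, 3), ]))$warnings),
               0L)
})

test_that("Q-matrix CSV round trip preserves entries and labels", {
  q <- build_design(hierarchy_shape("divergent", 3), "Q2", 10)
  f <- tempfile(fileext = ".csv")
  write_qmatrix(q, f)
  q2 <- read_qmatrix(f)
  expect_identical(q$entries, q2$entries)
  unlink(f)
})

test_that("degenerate Q-matrices are rejected", {
  expect_error(qmatrix(rbind(c(0, 0, 0), c(1, 0, 0))), "all-zero row")
  expect_warning(qmatrix(rbind(c(1, 0, 0), c(1, 0, 0))), "all-zero column")
  expect_error(qmatrix(rbind(c(2, 0, 1))), "binary")
})
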