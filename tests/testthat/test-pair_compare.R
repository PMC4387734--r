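test_that("correlation matrix: perfect, anti-perfect, and hand example", {
  # identical columns -> r = 1
  m <- result_matrix(matrix(rep(c(0.01, 0.2, 0.5), 2), ncol = 2,
                            dimnames = list(paste0("g", 1:3), c("a", "b"))))
  expect_equal(correlation_matrix(m)$r[1, 2], 1)

  # -log10 values (1,2,3) vs (3,2,1) -> r = -1
  m2 <- result_matrix(matrix(10^-c(1, 2, 3, 3, 2, 1), ncol = 2,
                             dimnames = list(paste0("g", 1:3),
                                             c("a", "b"))))
  expect_equal(correlation_matrix(m2)$r[1, 2], -1)

  # -log10 values (1,2,3) vs (1,3,2), Pearson -> r = 0.5 (hand evaluation)
  m3 <- result_matrix(matrix(10^-c(1, 2, 3, 1, 3, 2), ncol = 2,
                             dimnames = list(paste0("g", 1:3),
                                             c("a", "b"))))
  expect_equal(correlation_matrix(m3, "neglog10", "pearson")$r[1, 2], 0.5,
               tolerance = 1e-12)
})

test_that("correlation matrix structure: symmetry, diagonal, reordering", {
  m <- random_rm(21, max_m = 300, max_k = 5, max_missing = 0.2)
  cm <- correlation_matrix(m)
  expect_identical(cm$r, t(cm$r))
  expect_true(all(diag(cm$r) == 1))
  expect_true(all(abs(cm$r[!is.na(cm$r)]) <= 1 + 1e-12))
  # invariance under marker reordering
  perm <- sample(n_markers(m))
  cm2 <- correlation_matrix(m[perm, ])
  expect_equal(cm2$r, cm$r, tolerance = 1e-12)
  # n_used counts pair-complete markers
  obs <- !is.na(unclass(m))
  expect_identical(cm$n_used, crossprod(obs))
})

test_that("insufficient pair-complete markers give NA cells, not errors", {
  pv <- matrix(c(0.1, NA, NA, NA, 0.2, 0.3, 0.4, 0.5, 0.6), 3, 3,
               dimnames = list(paste0("g", 1:3), c("a", "b", "c")))
  cm <- correlation_matrix(result_matrix(pv))
  expect_true(is.na(cm$r["a", "b"]))   # only 1 shared marker
  expect_false(is.na(cm$r["b", "c"]))
})

test_that("spearman correlation is invariant to the transform", {
  m <- random_rm(22, max_m = 200, max_k = 4, max_missing = 0)
  r1 <- correlation_matrix(m, "neglog10", "spearman")$r
  r2 <- correlation_matrix(m, "raw", "spearman")$r
  expect_equal(abs(r1), abs(r2), tolerance = 1e-12)
})

test_that("classify_pair matches direct threshold evaluation", {
  m <- tiny_rm()
  pc <- classify_pair(m, "A", "B", 0.05)
  expect_identical(pc$both, "m1")
  expect_identical(pc$only_a, "m3")
  expect_identical(pc$only_b, "m2")
  expect_identical(pc$neither, character(0))

  # a method against itself: no exclusive markers
  pc2 <- classify_pair(m, "A", "A", 0.05)
  expect_identical(pc2$only_a, character(0))
  expect_identical(pc2$only_b, character(0))

  expect_error(classify_pair(m, "A", "nope", 0.05), "unknown method")
  expect_error(classify_pair(m, "A", "B", 0), "\\(0, 1\\)")
})

test_that("classify_pair partition equals the brute-force oracle", {
  for (seed in 1:8) {
    m <- random_rm(seed + 40, max_m = 1000, max_k = 4, max_missing = 0.2)
    meths <- sample(method_names(m), 2)
    ta <- sample(c(0.05, 0.01, 0.3), 1)
    tb <- sample(c(0.05, 0.001), 1)
    pc <- classify_pair(m, meths[1], meths[2], ta, tb)
    expect_same_partition(pc, oracle_classify(m, meths[1], meths[2], ta, tb))
    # conservation: four classes + not-comparable cover every marker once
    all_ids <- c(pc$both, pc$only_a, pc$only_b, pc$neither,
                 pc$not_comparable)
    expect_setequal(all_ids, marker_ids(m))
    expect_identical(anyDuplicated(all_ids), 0L)
  }
})

test_that("threshold_sweep counts match brute-force set intersections", {
  cuts <- c(0.05, 0.01, 0.001)
  for (seed in 1:5) {
    m <- random_rm(seed + 60, max_m = 500, max_k = 3, max_missing = 0.15)
    sw <- threshold_sweep(m, "method1", "method2", cuts)
    expect_identical(nrow(sw), 3L)
    for (i in seq_along(cuts)) {
      expect_identical(unlist(sw[i, -1]),
                       oracle_sweep_counts(m, "method1", "method2", cuts[i]))
    }
    # monotone n_both; constant row sums
    expect_true(all(diff(sw$n_both) <= 0))
    expect_equal(unname(unique(rowSums(sw[, -1]))),
                 sum(stats::complete.cases(
                   unclass(m)[, c("method1", "method2")])))
  }
})

test_that("nested thresholds example and cutoff validation", {
  pv <- matrix(rep(c(0.04, 0.009, 0.0009), 2), ncol = 2,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  sw <- threshold_sweep(result_matrix(pv), "a", "b", c(0.05, 0.01, 0.001))
  expect_identical(sw$n_both, c(3L, 2L, 1L))

  m <- tiny_rm()
  expect_error(threshold_sweep(m, "A", "B", c(0.01, 0.05)),
               "strictly decreasing")
  expect_error(threshold_sweep(m, "A", "B", c(0.05, 0.05)),
               "strictly decreasing")
  expect_error(threshold_sweep(m, "A", "B", numeric(0)), "\\(0, 1\\)")
})
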