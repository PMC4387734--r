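test_that("fisher_combine matches the closed-form chi-square tail", {
  # frozen hand value: ps = (0.05, 0.05) -> X^2 = -4 ln 0.05 = 11.98293...,
  # df = 4, p = e^(-X2/2) (1 + X2/2) = 0.01747871...
  fc <- fisher_combine(c(0.05, 0.05))
  expect_equal(fc$statistic, -4 * log(0.05), tolerance = 1e-12)
  expect_identical(fc$df, 4L)
  expect_equal(fc$p_value, 0.0174786613677700, tolerance = 1e-12)

  # k = 1 identity; boundary ps = (1, 1)
  expect_equal(fisher_combine(0.3)$p_value, 0.3, tolerance = 1e-14)
  fc1 <- fisher_combine(c(1, 1))
  expect_identical(fc1$statistic, 0)
  expect_identical(fc1$p_value, 1)

  # grid agreement with the independent even-df closed form
  set.seed(5)
  for (k in c(1, 2, 3, 5)) {
    for (rep in 1:20) {
      ps <- 10^stats::runif(k, -8, 0)
      expect_equal(fisher_combine(ps)$p_value, oracle_fisher_p(ps),
                   tolerance = 1e-12)
    }
  }
})

test_that("fisher_combine handles MISSING, zeros, and bad input", {
  fc <- fisher_combine(c(0.01, NA, 0.02))
  expect_identical(fc$k, 2L)
  expect_identical(fc$df, 4L)
  expect_equal(fc$p_value, oracle_fisher_p(c(0.01, 0.02)), tolerance = 1e-12)

  # zeros are clamped, not -Inf
  expect_true(is.finite(fisher_combine(c(0, 0.5))$statistic))
  expect_error(fisher_combine(numeric(0)), "no non-missing")
  expect_error(fisher_combine(NA_real_), "no non-missing")
  expect_error(fisher_combine(c(0.5, 2)), "\\[0, 1\\]")
  expect_true(fisher_combine(0.5, dependent_inputs = TRUE)$independence_warning)
})

test_that("fisher_combine properties: exchangeable, monotone, sharpening", {
  set.seed(6)
  for (rep in 1:10) {
    ps <- stats::runif(4)
    expect_equal(fisher_combine(ps)$p_value,
                 fisher_combine(rev(ps))$p_value)
    # strictly increasing in each component
    ps2 <- ps; ps2[2] <- min(1, ps[2] + 0.1)
    expect_gt(fisher_combine(ps2)$p_value, fisher_combine(ps)$p_value)
  }
  # combining k copies of a small p sharpens below p (this reverses for
  # large p: three copies of 0.6 combine to ~0.8, as the chi-square tail
  # dictates, so the property is only asserted on the small-p range)
  for (p in c(0.001, 0.04, 0.2)) {
    expect_lt(fisher_combine(rep(p, 3))$p_value, p)
  }
})

test_that("combined p of uniform nulls is itself uniform", {
  set.seed(7)
  reps <- 2000
  ps <- matrix(stats::runif(reps * 3), reps, 3)
  comb <- apply(ps, 1, function(r) fisher_combine(r)$p_value)
  expect_gt(stats::ks.test(comb, "punif")$p.value, 0.01)
})

test_that("color_for_cell implements the documented log ramp", {
  a <- 0.05; s <- 1e-10
  # threshold boundary: red at intensity 0
  c0 <- color_for_cell(a, a, s)
  expect_identical(c0$hue, "red")
  expect_equal(c0$intensity, 0)
  # saturation cap
  expect_equal(color_for_cell(1e-12, a, s)$intensity, 1)
  # geometric midpoint -> intensity 0.5 (direct log-ratio evaluation)
  expect_equal(color_for_cell(sqrt(a * s), a, s)$intensity, 0.5,
               tolerance = 1e-12)
  # p = 1: green, intensity 0
  c1 <- color_for_cell(1, a, s)
  expect_identical(c1$hue, "green")
  expect_identical(c1$intensity, 0)
  expect_error(color_for_cell(0.5, a, saturation_p = 0.1),
               "saturation_p")
})

test_that("color intensity is monotone non-increasing in p within each hue", {
  a <- 0.01
  p_red <- sort(10^seq(-12, log10(a), length.out = 30))
  i_red <- color_for_cell(p_red, a)$intensity
  expect_true(all(diff(i_red) <= 1e-12))
  p_green <- sort(seq(a + 1e-6, 1, length.out = 30))
  i_green <- color_for_cell(p_green, a)$intensity
  expect_true(all(diff(i_green) <= 1e-12))
  expect_identical(unique(color_for_cell(p_red, a)$hue), "red")
  expect_identical(unique(color_for_cell(p_green, a)$hue), "green")
})

test_that("build_multi_table flags, colors and ranks correctly", {
  pv <- matrix(c(0.01, 0.5, 0.2, 0.6), 2, 2,
               dimnames = list(c("g1", "g2"), c("a", "b")))
  mt <- build_multi_table(result_matrix(pv), thresholds = 0.05)
  expect_identical(rownames(mt$pvalues), c("g1", "g2"))  # ranked by avg p
  expect_identical(unname(mt$hue["g1", ]), c("red", "green"))
  expect_identical(unname(mt$hue["g2", ]), c("green", "green"))
  expect_identical(unname(mt$significant["g1", ]), c(TRUE, FALSE))

  # all p = 1 -> all green at intensity 0
  pv1 <- matrix(1, 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  mt1 <- build_multi_table(result_matrix(pv1), thresholds = 0.05)
  expect_true(all(mt1$hue == "green"))
  expect_true(all(mt1$intensity == 0))

  expect_error(build_multi_table(result_matrix(pv), thresholds =
                                   c(a = 0.05)), "covering")
  expect_error(build_multi_table(result_matrix(pv), methods = "a"),
               "at least 2")
})

test_that("multi-table flags equal brute-force per-cell comparison", {
  m <- random_rm(31, max_m = 300, max_k = 4, max_missing = 0.1)
  K <- n_methods(m)
  th <- stats::setNames(stats::runif(K, 0.001, 0.1), method_names(m))
  mt <- build_multi_table(m, thresholds = th, with_combined = TRUE)
  for (i in seq_len(nrow(mt$pvalues))) {
    for (j in seq_len(K)) {
      p <- mt$pvalues[i, j]
      meth <- colnames(mt$pvalues)[j]
      if (is.na(p)) {
        expect_true(is.na(mt$significant[i, j]))
      } else {
        expect_identical(mt$significant[i, j], p <= th[[meth]])
        expect_identical(mt$hue[i, j],
                         if (p <= th[[meth]]) "red" else "green")
      }
    }
    r <- mt$pvalues[i, ]
    if (!all(is.na(r)))
      expect_equal(unname(mt$combined_p[i]),
                   oracle_fisher_p(pmax(r[!is.na(r)], 1e-300)),
                   tolerance = 1e-10)
  }
  # row order follows ascending average p
  expect_true(!is.unsorted(mt$average_p[!is.na(mt$average_p)]))
})

test_that("common_significant equals explicit set intersection", {
  pv <- matrix(c(0.01, 0.01, 0.01, 0.9), 2, 2,
               dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_identical(common_significant(result_matrix(pv), thresholds = 0.05),
                   "g1")
  # saturated thresholds: every fully observed marker, ranked by avg p
  expect_identical(common_significant(result_matrix(pv),
                                      thresholds = 0.999999),
                   c("g1", "g2"))

  m <- random_rm(32, max_m = 800, max_k = 4, max_missing = 0.1)
  th <- 0.05
  got <- common_significant(m, thresholds = th)
  x <- unclass(m)
  sets <- lapply(seq_len(ncol(x)),
                 function(j) rownames(x)[!is.na(x[, j]) & x[, j] <= th])
  expect_setequal(got, Reduce(intersect, sets))
  # anti-monotone in the method set
  sub <- common_significant(m, method_names(m)[1:2], thresholds = th)
  expect_true(all(got %in% sub))
})
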