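# Independent oracles and fixture builders shared across the suite.
# Everything here deliberately avoids the package's own code paths (except
# where a fixture matrix is the input under test).

# small hand-built result matrix
tiny_rm <- function() {
  result_matrix(matrix(c(0.01, 0.20, 0.03,
                         0.04, 0.01, 0.50), ncol = 2,
                       dimnames = list(c("m1", "m2", "m3"), c("A", "B"))))
}

# random fixture via the package generator, with randomized shape/params
random_rm <- function(seed, max_m = 2000, max_k = 6, max_missing = 0.2) {
  set.seed(seed)
  M <- sample(5:max_m, 1)
  K <- sample(2:max_k, 1)
  simulate_pvalue_matrix(M, K,
                         rho = stats::runif(1, 0, 0.95),
                         pi1 = stats::runif(1, 0, 0.3),
                         mu = stats::runif(1, 0, 3),
                         missing_rate = stats::runif(1, 0, max_missing),
                         seed = seed + 7L)
}

# brute-force per-marker re-decision of the two-method Venn partition
# (one label per marker, decided in a plain loop, then split by label)
oracle_classify <- function(m, a, b, ta, tb) {
  x <- unclass(m)
  ids <- rownames(x)
  pa <- x[, a]; pb <- x[, b]
  label <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    label[i] <- if (is.na(pa[i]) || is.na(pb[i])) "not_comparable"
    else if (pa[i] <= ta && pb[i] <= tb) "both"
    else if (pa[i] <= ta) "only_a"
    else if (pb[i] <= tb) "only_b"
    else "neither"
  }
  list(both = ids[label == "both"],
       only_a = ids[label == "only_a"],
       only_b = ids[label == "only_b"],
       neither = ids[label == "neither"],
       not_comparable = ids[label == "not_comparable"])
}

# brute-force set-intersection counts for one sweep cutoff
oracle_sweep_counts <- function(m, a, b, cutoff) {
  x <- unclass(m)
  ok <- !is.na(x[, a]) & !is.na(x[, b])
  sa <- rownames(x)[ok & x[, a] <= cutoff]
  sb <- rownames(x)[ok & x[, b] <= cutoff]
  all_ok <- rownames(x)[ok]
  c(n_both = length(intersect(sa, sb)),
    n_only_a = length(setdiff(sa, sb)),
    n_only_b = length(setdiff(sb, sa)),
    n_neither = length(setdiff(all_ok, union(sa, sb))))
}

# closed-form chi-square upper tail at even df = 2k:
# P(X > x) = exp(-x/2) * sum_{j=0}^{k-1} (x/2)^j / j!
oracle_chisq_sf_even <- function(x, k) {
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

oracle_fisher_p <- function(ps) {
  x <- -2 * sum(log(ps))
  oracle_chisq_sf_even(x, length(ps))
}

# independent re-implementation of the correlated p-value generator:
# Cholesky of the full equicorrelation matrix instead of the one-factor
# construction, Bernoulli signal labels drawn up front
oracle_simulate_pvalues <- function(M, K, rho, pi1, mu, seed) {
  set.seed(seed)
  sigma <- matrix(rho, K, K); diag(sigma) <- 1
  L <- chol(sigma)
  z <- matrix(stats::rnorm(M * K), M, K) %*% L
  signal <- stats::rbinom(M, 1, pi1) == 1
  z[signal, ] <- z[signal, , drop = FALSE] + mu
  stats::pnorm(z, lower.tail = FALSE)
}

# mean off-diagonal Pearson correlation of -log10 p
mean_offdiag_cor <- function(p) {
  r <- stats::cor(-log10(pmax(p, 1e-300)), use = "pairwise.complete.obs")
  mean(r[upper.tri(r)])
}

expect_same_partition <- function(pc, oracle) {
  expect_identical(pc$both, oracle$both)
  expect_identical(pc$only_a, oracle$only_a)
  expect_identical(pc$only_b, oracle$only_b)
  expect_identical(pc$neither, oracle$neither)
  expect_identical(pc$not_comparable, oracle$not_comparable)
}
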