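#' Simulate a correlated multi-method p-value matrix
#'
#' Stands in for real multi-method result tables: for each marker a K-vector
#' of latent z-scores is drawn from an equicorrelated Gaussian (single
#' cross-method correlation \code{rho}); with probability \code{pi1} the
#' marker is a signal and all K coordinates are shifted by \code{mu}; each z
#' is converted to a one-sided p via the standard normal upper tail (so
#' \code{mu > 0} maps monotonically to small p-values). Missing values are
#' sprinkled completely at random at \code{missing_rate}. Under the null
#' (\code{pi1 = 0}) every column is exactly Uniform(0, 1).
#'
#' @param n_markers number of markers (rows), M.
#' @param n_methods number of methods (columns), K >= 2.
#' @param rho cross-method latent correlation in \code{[0, 1]}.
#' @param pi1 signal fraction in \code{[0, 1]}.
#' @param mu mean shift of signal z-scores (non-negative).
#' @param missing_rate fraction of cells set missing, in \code{[0, 1)}.
#' @param seed integer; fixes the full output. The caller's RNG state is
#'   left untouched.
#' @return a \code{result_matrix} with markers \code{m1..mM} and methods
#'   \code{method1..methodK}; signal markers recorded in the
#'   \code{"signal_markers"} attribute.
#' @export
simulate_pvalue_matrix <- function(n_markers, n_methods = 3, rho = 0,
                                   pi1 = 0, mu = 0, missing_rate = 0,
                                   seed = 1) {
  stopifnot(n_markers >= 1, n_methods >= 2,
            rho >= 0, rho <= 1, pi1 >= 0, pi1 <= 1, mu >= 0,
            missing_rate >= 0, missing_rate < 1)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old_seed), add = TRUE)
  set_sim_seed(seed)
  M <- as.integer(n_markers); K <- as.integer(n_methods)
  # equicorrelated Gaussian via a shared latent factor:
  # z = sqrt(rho) * f + sqrt(1 - rho) * e  has Cor(z_i, z_j) = rho
  f <- stats::rnorm(M)
  e <- matrix(stats::rnorm(M * K), M, K)
  z <- sqrt(rho) * f + sqrt(1 - rho) * e
  signal <- stats::runif(M) < pi1
  z[signal, ] <- z[signal, , drop = FALSE] + mu
  p <- stats::pnorm(z, lower.tail = FALSE)
  if (missing_rate > 0)
    p[stats::runif(M * K) < missing_rate] <- NA_real_
  ids <- paste0("m", seq_len(M))
  out <- result_matrix(p, marker_ids = ids,
                       method_names = paste0("method", seq_len(K)))
  attr(out, "signal_markers") <- ids[signal]
  out
}

#' Simulate two-group expression data and analyze it with three tests
#'
#' Emulates the structure of a case/control expression study: a genes x
#' samples Gaussian expression matrix where a fraction of genes is
#' mean-shifted in group 2, then per-gene p-values from (1) Welch's t-test,
#' (2) the Wilcoxon rank-sum test (normal approximation with tie
#' correction), and (3) a permutation test of the Welch t statistic over
#' label shuffles, with p = (b + 1) / (B + 1) so permutation p-values are
#' never zero. Returns real multi-test p-values so correlation and
#' concordance behaviour downstream is that of genuine analyses, not of a
#' copula.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (>= 2).
#' @param de_fraction fraction of genes differentially expressed.
#' @param fold_effect mean shift of DE genes, in units of \code{noise_sd}.
#' @param noise_sd residual standard deviation.
#' @param n_permutations number of label shuffles B.
#' @param seed integer seed; fixes the full output.
#' @return a genes x 3 \code{result_matrix} with methods \code{t_test},
#'   \code{wilcoxon}, \code{permutation}; true DE gene ids in the
#'   \code{"de_markers"} attribute.
#' @export
simulate_two_group <- function(n_genes, n_per_group, de_fraction = 0.1,
                               fold_effect = 2, noise_sd = 1,
                               n_permutations = 1000, seed = 1) {
  stopifnot(n_genes >= 1, de_fraction >= 0, de_fraction <= 1,
            noise_sd > 0, n_permutations >= 1)
  if (n_per_group < 2)
    stop("`n_per_group` must be at least 2", call. = FALSE)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old_seed), add = TRUE)
  set_sim_seed(seed)
  G <- as.integer(n_genes); n <- as.integer(n_per_group)
  de <- stats::runif(G) < de_fraction
  x <- matrix(stats::rnorm(G * 2 * n, sd = noise_sd), G, 2 * n)
  g2 <- seq_len(n) + n
  x[de, g2] <- x[de, g2, drop = FALSE] + fold_effect * noise_sd
  labels <- rep(c(1L, 2L), each = n)

  t_obs <- welch_t_rows(x, labels == 1L)
  p_t <- 2 * stats::pt(abs(t_obs$stat), df = t_obs$df, lower.tail = FALSE)

  p_w <- wilcoxon_rows(x, labels == 1L)

  # permutation null of |t|: shared label shuffles across genes, vectorized
  B <- as.integer(n_permutations)
  exceed <- integer(G)
  block <- 200L
  done <- 0L
  abs_obs <- abs(t_obs$stat)
  while (done < B) {
    b <- min(block, B - done)
    perm1 <- vapply(seq_len(b), function(i) {
      w <- logical(2L * n); w[sample.int(2L * n, n)] <- TRUE; w
    }, logical(2L * n))
    for (i in seq_len(b)) {
      tp <- welch_t_rows(x, perm1[, i])
      exceed <- exceed + (abs(tp$stat) >= abs_obs)
    }
    done <- done + b
  }
  p_perm <- (exceed + 1) / (B + 1)

  p <- cbind(t_test = pmin(p_t, 1), wilcoxon = p_w, permutation = p_perm)
  ids <- paste0("gene", seq_len(G))
  out <- result_matrix(p, marker_ids = ids,
                       method_names = c("t_test", "wilcoxon", "permutation"))
  attr(out, "de_markers") <- ids[de]
  out
}

# internal: Welch t statistic for every row of x, group 1 = cols with g1 TRUE
welch_t_rows <- function(x, g1) {
  n1 <- sum(g1); n2 <- sum(!g1)
  x1 <- x[, g1, drop = FALSE]; x2 <- x[, !g1, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- (rowSums(x1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (rowSums(x2^2) - n2 * m2^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(stat = stat, df = df)
}

# internal: two-sided Wilcoxon rank-sum p per row, normal approximation with
# tie correction and continuity correction (the large-sample form)
wilcoxon_rows <- function(x, g1) {
  n1 <- sum(g1); n2 <- sum(!g1); N <- n1 + n2
  apply(x, 1L, function(row) {
    r <- rank(row)
    W <- sum(r[g1]) - n1 * (n1 + 1) / 2          # Mann-Whitney U for group 1
    ties <- table(row)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * (N + 1 - tie_term)
    if (sigma2 <= 0) return(1)
    z <- (W - n1 * n2 / 2 - sign(W - n1 * n2 / 2) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  })
}

# internal: seed validation + set
set_sim_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  set.seed(as.integer(seed %% .Machine$integer.max))
}

# internal: put the caller's RNG state back
restore_rng <- function(old_seed) {
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  else if (exists(".Random.seed", globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
}
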