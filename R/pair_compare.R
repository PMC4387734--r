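#' All-pairs correlation of method results
#'
#' Computes a K x K matrix of correlation coefficients between the methods'
#' p-values over pair-complete markers, after an optional \code{-log10}
#' transform (the conventional scale for p-value scatterplots; the clamp
#' floor makes it total). Cells with fewer than 2 pair-complete markers are
#' \code{NA}. The diagonal is exactly 1 wherever defined.
#'
#' @param m a \code{result_matrix} with at least 2 methods.
#' @param transform \code{"neglog10"} (default) or \code{"raw"}.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param floor clamp for zero p-values before the log transform.
#' @return an object of class \code{pv_correlation}: list with \code{r}
#'   (K x K correlation matrix), \code{n_used} (pair-complete marker counts),
#'   \code{transform}, \code{method}, \code{method_names}.
#' @export
correlation_matrix <- function(m, transform = c("neglog10", "raw"),
                               method = c("pearson", "spearman"),
                               floor = 1e-300) {
  validate_rm(m, need_k2 = TRUE)
  transform <- match.arg(transform)
  method <- match.arg(method)
  x <- unclass(m)
  x[] <- transform_pvalues(x, transform, floor)
  obs <- !is.na(x)
  n_used <- crossprod(obs)
  if (nrow(x) >= 2) {
    r <- suppressWarnings(
      stats::cor(x, use = "pairwise.complete.obs", method = method))
  } else {
    r <- matrix(NA_real_, ncol(x), ncol(x),
                dimnames = list(colnames(x), colnames(x)))
  }
  r[n_used < 2] <- NA_real_
  # constant columns give NaN under cor(); treat as undefined
  r[is.nan(r)] <- NA_real_
  diag(r)[diag(n_used) >= 2] <- 1
  structure(list(r = r, n_used = n_used, transform = transform,
                 method = method, method_names = colnames(x)),
            class = "pv_correlation")
}

#' @export
print.pv_correlation <- function(x, ...) {
  cat(sprintf("pairwise %s correlation of %s p-values (%d methods)\n",
              x$method,
              if (x$transform == "neglog10") "-log10" else "raw",
              length(x$method_names)))
  print(round(x$r, 3))
  invisible(x)
}

#' Two-method Venn partition of markers at given thresholds
#'
#' Splits the pair-complete markers into the four Venn classes: significant
#' under both methods, under A only, under B only, or neither. Significance
#' is inclusive (\code{p <= alpha}). Markers missing in either method are
#' excluded from the partition and reported in \code{not_comparable}.
#'
#' @param m a \code{result_matrix}.
#' @param method_a,method_b method names (columns of \code{m}).
#' @param threshold_a,threshold_b significance cut-offs in \code{(0, 1)};
#'   \code{threshold_b} defaults to \code{threshold_a}.
#' @return an object of class \code{pair_classification}: list with the four
#'   disjoint marker-id vectors (\code{both}, \code{only_a}, \code{only_b},
#'   \code{neither}; input order preserved), \code{not_comparable}, the
#'   method names and thresholds.
#' @export
classify_pair <- function(m, method_a, method_b,
                          threshold_a = 0.05, threshold_b = threshold_a) {
  validate_rm(m, need_k2 = TRUE)
  idx <- method_index(m, c(method_a, method_b))
  check_alpha(threshold_a)
  check_alpha(threshold_b)
  pa <- unclass(m)[, idx[1]]
  pb <- unclass(m)[, idx[2]]
  ok <- !is.na(pa) & !is.na(pb)
  sa <- pa[ok] <= threshold_a
  sb <- pb[ok] <= threshold_b
  ids <- rownames(m)[ok]
  structure(list(method_a = method_a, method_b = method_b,
                 threshold_a = threshold_a, threshold_b = threshold_b,
                 both = ids[sa & sb],
                 only_a = ids[sa & !sb],
                 only_b = ids[!sa & sb],
                 neither = ids[!sa & !sb],
                 not_comparable = rownames(m)[!ok]),
            class = "pair_classification")
}

#' @export
print.pair_classification <- function(x, ...) {
  cat(sprintf("pair classification: %s (alpha=%g) vs %s (alpha=%g)\n",
              x$method_a, x$threshold_a, x$method_b, x$threshold_b))
  cat(sprintf("  both: %d  only %s: %d  only %s: %d  neither: %d",
              length(x$both), x$method_a, length(x$only_a),
              x$method_b, length(x$only_b), length(x$neither)))
  if (length(x$not_comparable))
    cat(sprintf("  (not comparable: %d)", length(x$not_comparable)))
  cat("\n")
  invisible(x)
}

# internal
check_alpha <- function(a) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0 || a >= 1)
    stop("significance threshold must be a single value in (0, 1), got: ",
         deparse(substitute(a)), " = ", a, call. = FALSE)
  invisible(a)
}

#' Threshold sweep over a decreasing grid of cut-offs
#'
#' Recomputes the two-method Venn partition counts at each cut-off (the same
#' threshold applied to both methods), summarizing how the common and
#' exclusive significant sets shrink as the cut-off tightens.
#'
#' @param m a \code{result_matrix}.
#' @param method_a,method_b method names.
#' @param cutoffs strictly decreasing vector of thresholds in \code{(0, 1)};
#'   default \code{c(0.05, 0.01, 0.005, 0.001)}.
#' @return an object of class \code{sweep_table}: a data.frame with columns
#'   \code{cutoff}, \code{n_both}, \code{n_only_a}, \code{n_only_b},
#'   \code{n_neither}, plus attributes naming the methods.
#' @export
threshold_sweep <- function(m, method_a, method_b,
                            cutoffs = c(0.05, 0.01, 0.005, 0.001)) {
  validate_rm(m, need_k2 = TRUE)
  if (!is.numeric(cutoffs) || !length(cutoffs) ||
      any(is.na(cutoffs)) || any(cutoffs <= 0) || any(cutoffs >= 1))
    stop("`cutoffs` must be values in (0, 1)", call. = FALSE)
  if (length(cutoffs) > 1 && any(diff(cutoffs) >= 0))
    stop("`cutoffs` must be strictly decreasing", call. = FALSE)
  rows <- lapply(cutoffs, function(a) {
    pc <- classify_pair(m, method_a, method_b, a, a)
    data.frame(cutoff = a,
               n_both = length(pc$both),
               n_only_a = length(pc$only_a),
               n_only_b = length(pc$only_b),
               n_neither = length(pc$neither))
  })
  out <- do.call(rbind, rows)
  structure(out, method_a = method_a, method_b = method_b,
            class = c("sweep_table", "data.frame"))
}
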