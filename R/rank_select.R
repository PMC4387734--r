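#' Average p-value per marker
#'
#' Arithmetic mean over the non-missing entries of each marker's row; a
#' marker whose row is entirely missing gets \code{NA}. This is the ranking
#' statistic used to pick the "top N" markers for display.
#'
#' @param m a \code{result_matrix}.
#' @param markers marker ids to evaluate; default all.
#' @return named numeric vector of row means in \code{[0, 1]} (or NA).
#' @export
average_pvalue <- function(m, markers = marker_ids(m)) {
  validate_rm(m)
  idx <- match(markers, rownames(m))
  if (anyNA(idx))
    stop("unknown marker id(s): ",
         paste(markers[is.na(idx)], collapse = ", "), call. = FALSE)
  rowMeans(unclass(m)[idx, , drop = FALSE], na.rm = TRUE) |>
    (\(v) { v[is.nan(v)] <- NA_real_; v })()
}

#' Select the top markers by average p-value
#'
#' Keeps the \code{min(N, M)} markers with the smallest average p-value
#' (raw p, not -log10). Percent mode keeps \code{ceiling(M * percent/100)}
#' markers. Ties break by original input order (stable); all-missing rows
#' sort last. The selected markers are returned in their original order.
#'
#' @param m a \code{result_matrix}.
#' @param n positive integer count, or \code{NULL}.
#' @param percent value in \code{(0, 100]}, or \code{NULL}. Exactly one of
#'   \code{n} / \code{percent} may be given; both \code{NULL} selects all.
#' @return a \code{result_matrix} sub-matrix.
#' @export
select_top <- function(m, n = NULL, percent = NULL) {
  validate_rm(m)
  if (!is.null(n) && !is.null(percent))
    stop("give either `n` or `percent`, not both", call. = FALSE)
  M <- nrow(m)
  if (is.null(n) && is.null(percent)) return(m)
  if (!is.null(percent)) {
    if (!is.numeric(percent) || length(percent) != 1L ||
        percent <= 0 || percent > 100)
      stop("`percent` must be in (0, 100]", call. = FALSE)
    n <- ceiling(M * percent / 100)
  } else {
    if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
      stop("`n` must be a positive integer", call. = FALSE)
  }
  n <- min(as.integer(n), M)
  avg <- average_pvalue(m)
  # NA (all-missing rows) last; stable order within ties
  ord <- order(is.na(avg), avg)
  keep <- sort(ord[seq_len(n)])
  m[keep, , drop = FALSE]
}
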