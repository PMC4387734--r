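#' Fisher's combined probability test
#'
#' Combines k p-values via \eqn{X^2 = -2 \sum \ln p_i}, referred to a
#' chi-square distribution with \eqn{2k} degrees of freedom. Missing values
#' are dropped (k counts survivors); zeros are floor-clamped before the log.
#'
#' Fisher's method assumes the combined p-values are independent. When the
#' inputs are several methods' results on one dataset that assumption is
#' violated and the combined p is a descriptive summary, not a valid test;
#' set \code{dependent_inputs = TRUE} to record that caveat in the result
#' (reports print it as a footer warning).
#'
#' @param ps numeric vector of p-values in \code{(0, 1]} (zeros clamped).
#' @param floor clamp applied to zeros before \code{log}.
#' @param dependent_inputs flag: the p-values come from one dataset analyzed
#'   by multiple methods, so the independence assumption fails.
#' @return an object of class \code{fisher_combined}: list with
#'   \code{statistic} (X^2), \code{df} (= 2k), \code{p_value},
#'   \code{k}, \code{independence_warning}.
#' @examples
#' fisher_combine(c(0.05, 0.05))  # X^2 ~ 11.98, p ~ 0.0175
#' @export
fisher_combine <- function(ps, floor = 1e-300, dependent_inputs = FALSE) {
  if (!is.numeric(ps)) stop("`ps` must be numeric", call. = FALSE)
  ps <- ps[!is.na(ps)]
  if (!length(ps))
    stop("no non-missing p-values to combine", call. = FALSE)
  if (any(ps < 0 | ps > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  ps <- clamp_pvalues(ps, floor)
  k <- length(ps)
  x2 <- -2 * sum(log(ps))
  structure(list(statistic = x2, df = 2L * k,
                 p_value = stats::pchisq(x2, df = 2 * k, lower.tail = FALSE),
                 k = k, independence_warning = isTRUE(dependent_inputs)),
            class = "fisher_combined")
}

#' @export
print.fisher_combined <- function(x, ...) {
  cat(sprintf("Fisher combined: X^2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (x$independence_warning)
    cat("note: inputs from one dataset analyzed by multiple methods;",
        "independence is violated, interpret with caution\n")
  invisible(x)
}

#' Red/green color code for a significance-table cell
#'
#' Hue is red iff \code{p <= alpha}, green otherwise. Intensity is
#' logarithmic in p: for significant cells it ramps from 0 at the threshold
#' to 1 at a saturation point (default 1e-10), i.e.
#' \code{log10(alpha / p) / log10(alpha / saturation_p)} capped at 1; for
#' non-significant cells it is 0 at \code{p >= 0.5} and ramps up toward the
#' threshold boundary on the same log scale. So within each hue, a smaller p
#' is more intensely colored.
#'
#' @param p p-value(s) in \code{[0, 1]}.
#' @param alpha significance threshold in \code{(0, 1)}.
#' @param saturation_p p at which red reaches full intensity; in
#'   \code{(0, alpha)}.
#' @param floor clamp for zero p-values.
#' @return a data.frame with columns \code{hue} ("red"/"green"),
#'   \code{intensity} in \code{[0, 1]}, and \code{hex} (white-to-hue ramp),
#'   one row per element of \code{p}.
#' @export
color_for_cell <- function(p, alpha = 0.05, saturation_p = 1e-10,
                           floor = 1e-300) {
  check_alpha(alpha)
  if (!is.numeric(saturation_p) || length(saturation_p) != 1L ||
      saturation_p <= 0 || saturation_p >= alpha)
    stop("`saturation_p` must lie in (0, alpha)", call. = FALSE)
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  pc <- clamp_pvalues(p, floor)
  sig <- !is.na(pc) & pc <= alpha
  intensity <- rep(NA_real_, length(p))
  intensity[sig] <- pmin(1, log10(alpha / pc[sig]) /
                            log10(alpha / saturation_p))
  if (any(!sig & !is.na(pc))) {
    ns <- which(!sig & !is.na(pc))
    if (alpha < 0.5) {
      intensity[ns] <- pmin(1, pmax(0, log10(0.5 / pc[ns]) /
                                       log10(0.5 / alpha)))
    } else intensity[ns] <- 0
  }
  hue <- ifelse(sig, "red", "green")
  hue[is.na(pc)] <- NA_character_
  hex <- rep(NA_character_, length(p))
  ok <- !is.na(hue)
  base <- ifelse(hue[ok] == "red", "#cc0000", "#00aa44")
  hex[ok] <- mix_with_white(base, intensity[ok])
  data.frame(hue = hue, intensity = intensity, hex = hex,
             stringsAsFactors = FALSE)
}

# internal: linear ramp from white (intensity 0) to the base hue (1)
mix_with_white <- function(hex_base, w) {
  rgb_b <- grDevices::col2rgb(hex_base)
  mixed <- round(255 * (1 - w) + t(rgb_b) * w)
  grDevices::rgb(mixed[, 1], mixed[, 2], mixed[, 3], maxColorValue = 255)
}

# internal: normalize a thresholds spec to a named vector covering `methods`
resolve_thresholds <- function(thresholds, methods) {
  if (is.numeric(thresholds) && length(thresholds) == 1L &&
      is.null(names(thresholds))) {
    thresholds <- stats::setNames(rep(thresholds, length(methods)), methods)
  }
  if (is.null(names(thresholds)) || !all(methods %in% names(thresholds)))
    stop("`thresholds` must be a single alpha or a named vector covering ",
         "every selected method; missing: ",
         paste(setdiff(methods, names(thresholds)), collapse = ", "),
         call. = FALSE)
  th <- thresholds[methods]
  for (a in th) check_alpha(a)
  th
}

#' Multi-method color-coded significance table
#'
#' Simultaneous comparison of two or more methods, each with its own
#' significance level: one row per marker (sorted by ascending average
#' p-value over the selected methods), one column per method, each cell
#' carrying the p-value, a significance flag (\code{p <= alpha}), and a
#' red/green color code whose intensity reflects the degree of significance.
#' Optionally adds a per-marker Fisher combined p-value.
#'
#' @param m a \code{result_matrix}.
#' @param methods subset of method names to compare (>= 2); default all.
#' @param thresholds single alpha applied to every method, or a named vector
#'   \code{c(method = alpha, ...)} covering all selected methods.
#' @param with_combined add the Fisher combined p column. Because the
#'   methods were run on one dataset the combined p violates the
#'   independence assumption; it is a descriptive summary and rendered
#'   reports carry a caution footer.
#' @param saturation_p,floor passed to \code{\link{color_for_cell}}.
#' @return an object of class \code{multi_table}: list with \code{pvalues}
#'   (markers x methods, sorted), \code{significant} (logical grid),
#'   \code{hue}, \code{intensity}, \code{hex} (character/numeric grids),
#'   \code{average_p}, \code{combined_p} (or NULL), \code{thresholds}.
#' @export
build_multi_table <- function(m, methods = method_names(m), thresholds = 0.05,
                              with_combined = FALSE, saturation_p = 1e-10,
                              floor = 1e-300) {
  validate_rm(m, need_k2 = TRUE)
  if (length(methods) < 2)
    stop("select at least 2 methods", call. = FALSE)
  idx <- method_index(m, methods)
  th <- resolve_thresholds(thresholds, methods)
  sub <- m[, idx, drop = FALSE]
  avg <- average_pvalue(sub)
  ord <- order(is.na(avg), avg)
  sub <- sub[ord, , drop = FALSE]
  avg <- avg[ord]
  pv <- unclass(sub)
  sig <- sweep(pv, 2L, th, `<=`)
  hue <- hex <- array(NA_character_, dim = dim(pv), dimnames = dimnames(pv))
  intensity <- array(NA_real_, dim = dim(pv), dimnames = dimnames(pv))
  for (j in seq_along(methods)) {
    cc <- color_for_cell(pv[, j], th[j], saturation_p, floor)
    hue[, j] <- cc$hue
    intensity[, j] <- cc$intensity
    hex[, j] <- cc$hex
  }
  combined <- NULL
  if (isTRUE(with_combined)) {
    combined <- apply(pv, 1L, function(r) {
      if (all(is.na(r))) NA_real_
      else fisher_combine(r, floor, dependent_inputs = TRUE)$p_value
    })
  }
  structure(list(pvalues = pv, significant = sig, hue = hue,
                 intensity = intensity, hex = hex, average_p = avg,
                 combined_p = combined, thresholds = th,
                 methods = methods),
            class = "multi_table")
}

#' @export
print.multi_table <- function(x, n = 10L, ...) {
  cat(sprintf("multi-method significance table: %d markers x %d methods\n",
              nrow(x$pvalues), length(x$methods)))
  cat("thresholds:",
      paste(sprintf("%s=%g", x$methods, x$thresholds), collapse = ", "), "\n")
  k <- min(n, nrow(x$pvalues))
  if (k > 0) {
    df <- as.data.frame(x$pvalues[seq_len(k), , drop = FALSE])
    df$avg_p <- x$average_p[seq_len(k)]
    if (!is.null(x$combined_p)) df$combined_p <- x$combined_p[seq_len(k)]
    print(df)
  }
  if (nrow(x$pvalues) > k) cat("...", nrow(x$pvalues) - k, "more markers\n")
  if (!is.null(x$combined_p))
    cat("note: combined p assumes independent inputs; methods applied to",
        "one dataset violate this -- interpret with caution\n")
  invisible(x)
}

#' Markers significant under every selected method
#'
#' The intersection of the per-method significant sets -- the recommended
#' candidate list for downstream validation -- ranked by ascending average
#' p-value over the selected methods. Markers with a missing p-value in any
#' selected method cannot qualify.
#'
#' @inheritParams build_multi_table
#' @return character vector of marker ids, best (smallest average p) first.
#' @export
common_significant <- function(m, methods = method_names(m),
                               thresholds = 0.05) {
  validate_rm(m, need_k2 = TRUE)
  if (length(methods) < 2)
    stop("select at least 2 methods", call. = FALSE)
  idx <- method_index(m, methods)
  th <- resolve_thresholds(thresholds, methods)
  pv <- unclass(m)[, idx, drop = FALSE]
  sig <- sweep(pv, 2L, th, `<=`)
  hit <- rowSums(sig, na.rm = FALSE) == length(methods)
  hit[is.na(hit)] <- FALSE
  ids <- rownames(m)[hit]
  avg <- rowMeans(pv[hit, , drop = FALSE], na.rm = TRUE)
  ids[order(avg, match(ids, rownames(m)))]
}
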