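#' @name report
#' @title Static report rendering
#' @description Renderers for the three comparison views. Each writes its
#'   files into an output directory and returns a \code{report_bundle}
#'   manifest (data.frame of name, kind, path). TSV and HTML output is a
#'   pure function of the inputs, so re-rendering identical inputs yields
#'   byte-identical files.
NULL

# colors for the two-method scatter classes: A-only red, B-only blue,
# both purple, neither grey -- configurable for accessibility
default_class_colors <- c(only_a = "#cc0000", only_b = "#2244cc",
                          both = "#882299", neither = "#bbbbbb")

new_bundle <- function(out_dir, names, kinds) {
  paths <- file.path(out_dir, names)
  stopifnot(all(file.exists(paths)))
  structure(data.frame(name = names, kind = kinds, path = paths,
                       stringsAsFactors = FALSE),
            class = c("report_bundle", "data.frame"))
}

write_tsv_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

df_to_tsv <- function(df, path) {
  cells <- vapply(df, function(col) {
    if (is.numeric(col))
      vapply(col, function(v) if (is.na(v)) "NA"
             else format(v, digits = 17, scientific = NA), character(1))
    else { col <- as.character(col); col[is.na(col)] <- "NA"; col }
  }, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  write_tsv_lines(c(paste(colnames(df), collapse = "\t"),
                    apply(cells, 1L, paste, collapse = "\t")), path)
}

open_device <- function(path, width, height) {
  if (grepl("\\.svg$", path)) {
    grDevices::svg(path, width = width, height = height)
  } else {
    grDevices::png(path, width = width * 96, height = height * 96, res = 96)
  }
}

#' Render the all-pairs view: scatter matrix image + correlation TSV
#'
#' One K x K panel image (off-diagonal panels scatter the transformed
#' p-values of each method pair, annotated with the correlation coefficient)
#' plus a TSV of the correlation matrix.
#'
#' @param corr a \code{pv_correlation} from \code{\link{correlation_matrix}}.
#' @param m the \code{result_matrix} the correlations came from.
#' @param out_dir output directory (created if needed).
#' @param image_format \code{"png"} or \code{"svg"}.
#' @return a \code{report_bundle} manifest.
#' @export
render_pairwise <- function(corr, m, out_dir, image_format = c("png", "svg")) {
  stopifnot(inherits(corr, "pv_correlation"))
  validate_rm(m, need_k2 = TRUE)
  if (nrow(m) == 0)
    stop("cannot render pairwise view: the result matrix has no markers",
         call. = FALSE)
  image_format <- match.arg(image_format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  r <- corr$r
  tsv <- data.frame(method = rownames(r), as.data.frame(r),
                    check.names = FALSE)
  df_to_tsv(tsv, file.path(out_dir, "correlations.tsv"))

  x <- unclass(m)
  x[] <- transform_pvalues(x, corr$transform)
  img <- paste0("pairwise_scatter.", image_format)
  open_device(file.path(out_dir, img), 7, 7)
  on.exit(grDevices::dev.off(), add = TRUE)
  lab <- if (corr$transform == "neglog10") "-log10 p" else "p"
  graphics::pairs(
    x, gap = 0.3, pch = 16, cex = 0.4, col = "#33557788",
    main = sprintf("pairwise %s correlation (%s)", corr$method, lab),
    upper.panel = function(xx, yy, ...) {
      graphics::points(xx, yy, pch = 16, cex = 0.4, col = "#33557788")
      ok <- stats::complete.cases(xx, yy)
      rr <- if (sum(ok) >= 2) suppressWarnings(
        stats::cor(xx[ok], yy[ok], method = corr$method)) else NA
      graphics::legend("topleft", bty = "n", cex = 0.9,
                       legend = sprintf("r = %.3f", rr))
    })
  new_bundle(out_dir, c("correlations.tsv", img), c("tsv", "image"))
}

#' Render the two-method detail view
#'
#' Writes the classified scatter plot (both/only-A/only-B/neither in
#' purple/red/blue/grey), a two-set Venn diagram with the three counts, the
#' threshold-sweep TSV, and one TSV marker list per Venn class.
#'
#' @param pc a \code{pair_classification} from \code{\link{classify_pair}}.
#' @param sweep a \code{sweep_table} from \code{\link{threshold_sweep}}
#'   (same method pair).
#' @param m the underlying \code{result_matrix}.
#' @param out_dir output directory.
#' @param image_format \code{"png"} or \code{"svg"}.
#' @param class_colors named vector of colors for
#'   \code{only_a,only_b,both,neither}.
#' @return a \code{report_bundle} manifest.
#' @export
render_detail <- function(pc, sweep, m, out_dir,
                          image_format = c("png", "svg"),
                          class_colors = default_class_colors) {
  stopifnot(inherits(pc, "pair_classification"),
            inherits(sweep, "sweep_table"))
  validate_rm(m, need_k2 = TRUE)
  image_format <- match.arg(image_format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  df_to_tsv(as.data.frame(sweep), file.path(out_dir, "sweep.tsv"))
  lists <- c("both", "only_a", "only_b", "neither")
  for (cls in lists) {
    ids <- pc[[cls]]
    avg <- if (length(ids)) unname(average_pvalue(m, ids)) else numeric(0)
    df_to_tsv(data.frame(marker = if (length(ids)) ids else character(0),
                         average_p = avg),
              file.path(out_dir, paste0("markers_", cls, ".tsv")))
  }

  # classified scatter
  idx <- method_index(m, c(pc$method_a, pc$method_b))
  xa <- transform_pvalues(unclass(m)[, idx[1]])
  xb <- transform_pvalues(unclass(m)[, idx[2]])
  cls_of <- rep(NA_character_, nrow(m))
  names(cls_of) <- rownames(m)
  for (cls in lists) cls_of[pc[[cls]]] <- cls
  img1 <- paste0("detail_scatter.", image_format)
  open_device(file.path(out_dir, img1), 6, 6)
  graphics::plot(xa, xb, pch = 16, cex = 0.5,
                 col = unname(class_colors[cls_of]),
                 xlab = paste0("-log10 p (", pc$method_a, ")"),
                 ylab = paste0("-log10 p (", pc$method_b, ")"),
                 main = sprintf("%s vs %s (alpha %g / %g)", pc$method_a,
                                pc$method_b, pc$threshold_a, pc$threshold_b))
  graphics::abline(v = -log10(pc$threshold_a), h = -log10(pc$threshold_b),
                   lty = 2, col = "grey40")
  graphics::legend("topright", bty = "n", pch = 16, cex = 0.8,
                   col = unname(class_colors[lists]),
                   legend = c("both", paste0(pc$method_a, " only"),
                              paste0(pc$method_b, " only"), "neither"))
  grDevices::dev.off()

  img2 <- paste0("venn.", image_format)
  open_device(file.path(out_dir, img2), 6, 5)
  draw_venn2(length(pc$only_a), length(pc$only_b), length(pc$both),
             pc$method_a, pc$method_b,
             c(class_colors[["only_a"]], class_colors[["only_b"]]))
  grDevices::dev.off()

  new_bundle(out_dir,
             c("sweep.tsv", paste0("markers_", lists, ".tsv"), img1, img2),
             c("tsv", rep("tsv", 4), "image", "image"))
}

# internal: two-circle Venn with region counts
draw_venn2 <- function(n_a, n_b, n_both, label_a, label_b,
                       colors = c("#cc000055", "#2244cc55")) {
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 10), ylim = c(0, 8), asp = 1)
  graphics::symbols(c(4, 6), c(4, 4), circles = c(2.2, 2.2),
                    inches = FALSE, add = TRUE,
                    bg = grDevices::adjustcolor(colors, alpha.f = 0.35),
                    fg = "grey30")
  graphics::text(3.0, 4, n_a, cex = 1.4)
  graphics::text(7.0, 4, n_b, cex = 1.4)
  graphics::text(5.0, 4, n_both, cex = 1.4)
  graphics::text(3.4, 6.6, label_a, cex = 1.0)
  graphics::text(6.6, 6.6, label_b, cex = 1.0)
  graphics::title(main = "significant markers")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the multi-method view: color-coded HTML table + TSV twin
#'
#' The HTML file has one row per marker, one cell per method styled with the
#' red/green intensity color, annotation links on marker ids where
#' available, an optional combined-p column, and -- whenever the combined
#' column is present -- a footer cautioning that Fisher's method assumes
#' independent inputs, which several methods on one dataset violate. The
#' TSV twin carries the p-values, flags and combined p in plain text.
#'
#' @param mt a \code{multi_table} from \code{\link{build_multi_table}}.
#' @param out_dir output directory.
#' @param title heading for the HTML page.
#' @return a \code{report_bundle} manifest.
#' @export
render_multi <- function(mt, out_dir, title = "multi-method comparison") {
  stopifnot(inherits(mt, "multi_table"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pv <- mt$pvalues
  methods <- mt$methods

  tsv <- data.frame(marker = rownames(pv), check.names = FALSE)
  for (j in seq_along(methods)) {
    tsv[[paste0("p_", methods[j])]] <- pv[, j]
    tsv[[paste0("sig_", methods[j])]] <-
      ifelse(is.na(mt$significant[, j]), "NA",
             ifelse(mt$significant[, j], "yes", "no"))
  }
  tsv$average_p <- mt$average_p
  if (!is.null(mt$combined_p)) tsv$combined_p <- mt$combined_p
  df_to_tsv(tsv, file.path(out_dir, "multi_table.tsv"))

  common <- common_significant(
    structure(pv, class = "result_matrix"), methods, mt$thresholds)
  avg_common <- rowMeans(pv[common, , drop = FALSE], na.rm = TRUE)
  df_to_tsv(data.frame(marker = common, average_p = unname(avg_common)),
            file.path(out_dir, "common_significant.tsv"))

  urls <- annotation_url(rownames(pv), "ncbi")
  head_cells <- c("marker",
                  sprintf("%s<br/><small>&alpha; = %g</small>",
                          html_escape(methods), mt$thresholds))
  if (!is.null(mt$combined_p)) head_cells <- c(head_cells, "combined p")
  rows <- vapply(seq_len(nrow(pv)), function(i) {
    id <- html_escape(rownames(pv)[i])
    idcell <- if (!is.na(urls[i]))
      sprintf('<a href="%s">%s</a>', urls[i], id) else id
    cells <- vapply(seq_along(methods), function(j) {
      p <- pv[i, j]
      if (is.na(p)) return('<td class="na">NA</td>')
      sprintf('<td style="background-color:%s">%s</td>',
              mt$hex[i, j], format(p, digits = 3))
    }, character(1))
    comb <- if (!is.null(mt$combined_p))
      sprintf("<td>%s</td>",
              if (is.na(mt$combined_p[i])) "NA"
              else format(mt$combined_p[i], digits = 3)) else ""
    sprintf("<tr><td>%s</td>%s%s</tr>", idcell,
            paste(cells, collapse = ""), comb)
  }, character(1))
  footer <- if (!is.null(mt$combined_p))
    paste0("<p class=\"caution\">Caution: Fisher&#39;s combined p-value ",
           "assumes independent inputs. When one dataset is analyzed by ",
           "multiple methods this assumption is violated; interpretation ",
           "of the combined p-value should be made with caution.</p>")
  else ""
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>%s</title>", html_escape(title)),
    "<style>",
    "body{font-family:sans-serif;margin:1.5em}",
    "table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:2px 8px;text-align:right}",
    "th{background:#eee}",
    "td.na{color:#999;text-align:center}",
    "p.caution{color:#884400;max-width:45em}",
    "</style></head><body>",
    sprintf("<h1>%s</h1>", html_escape(title)),
    "<p>Red cells: significant at the method&#39;s threshold; green:",
    "not significant. More significant p-values are colored more",
    "intensely. Rows are ordered by ascending average p-value.</p>",
    "<table>",
    sprintf("<tr>%s</tr>",
            paste(sprintf("<th>%s</th>", head_cells), collapse = "")),
    rows,
    "</table>",
    footer,
    "</body></html>")
  write_tsv_lines(html, file.path(out_dir, "multi_table.html"))
  new_bundle(out_dir,
             c("multi_table.tsv", "common_significant.tsv",
               "multi_table.html"),
             c("tsv", "tsv", "html"))
}
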