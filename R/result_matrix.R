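#' Construct a result matrix of p-values
#'
#' The central container of the package: a dense markers x methods grid of
#' p-values, one row per genetic marker (gene, probe, SNP, or collapsed
#' rare-variant region) and one column per analysis method. Missing entries
#' are stored as \code{NA}. Row order of the input is canonical: all ranking
#' ties downstream break by this order.
#'
#' @param pvalues numeric matrix with values in \code{[0, 1]} or \code{NA}.
#'   Row names are taken as marker ids and column names as method names when
#'   \code{marker_ids} / \code{method_names} are not given.
#' @param marker_ids character vector of unique marker identifiers.
#' @param method_names character vector of unique method labels.
#' @param source_path optional provenance string (file the matrix came from).
#' @return an object of class \code{result_matrix}: the validated numeric
#'   matrix with \code{dimnames} set and a \code{source_path} attribute.
#' @examples
#' m <- result_matrix(matrix(c(0.01, 0.5, 0.02, NA), 2, 2),
#'                    marker_ids = c("g1", "g2"),
#'                    method_names = c("T", "W"))
#' n_markers(m)
#' @export
result_matrix <- function(pvalues, marker_ids = rownames(pvalues),
                          method_names = colnames(pvalues),
                          source_path = NULL) {
  if (!is.matrix(pvalues) || !is.numeric(pvalues))
    stop("`pvalues` must be a numeric matrix", call. = FALSE)
  if (is.null(marker_ids) || is.null(method_names))
    stop("marker ids and method names are required (as arguments or dimnames)",
         call. = FALSE)
  marker_ids <- as.character(marker_ids)
  method_names <- as.character(method_names)
  if (length(marker_ids) != nrow(pvalues))
    stop("length of `marker_ids` must equal nrow(pvalues)", call. = FALSE)
  if (length(method_names) != ncol(pvalues))
    stop("length of `method_names` must equal ncol(pvalues)", call. = FALSE)
  dup <- marker_ids[duplicated(marker_ids)]
  if (length(dup))
    stop("duplicate marker id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(method_names))
    stop("duplicate method name(s): ",
         paste(unique(method_names[duplicated(method_names)]), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(pvalues)) + 1
    j <- ((bad[1] - 1) %/% nrow(pvalues)) + 1
    stop(sprintf("p-value out of [0,1] at marker '%s', method '%s': %g",
                 marker_ids[i], method_names[j], pvalues[bad[1]]),
         call. = FALSE)
  }
  dimnames(pvalues) <- list(marker_ids, method_names)
  structure(pvalues, source_path = source_path, class = "result_matrix")
}

#' @export
print.result_matrix <- function(x, ...) {
  cat(sprintf("result_matrix: %d markers x %d methods\n", nrow(x), ncol(x)))
  cat("methods:", paste(colnames(x), collapse = ", "), "\n")
  n_na <- sum(is.na(x))
  if (n_na) cat(sprintf("missing entries: %d (%.1f%%)\n",
                        n_na, 100 * n_na / length(x)))
  sp <- attr(x, "source_path")
  if (!is.null(sp)) cat("source:", sp, "\n")
  k <- min(6L, nrow(x))
  if (k > 0) print(unclass(x)[seq_len(k), , drop = FALSE])
  if (nrow(x) > k) cat("...", nrow(x) - k, "more markers\n")
  invisible(x)
}

#' @rdname result_matrix
#' @param m a \code{result_matrix}.
#' @export
n_markers <- function(m) nrow(m)

#' @rdname result_matrix
#' @export
n_methods <- function(m) ncol(m)

#' @rdname result_matrix
#' @export
marker_ids <- function(m) rownames(m)

#' @rdname result_matrix
#' @export
method_names <- function(m) colnames(m)

#' Subset a result matrix, preserving class and provenance
#'
#' @param x a \code{result_matrix}.
#' @param i,j row / column index as in \code{[.matrix}.
#' @param drop ignored; dimensions are always kept.
#' @param ... unused.
#' @export
`[.result_matrix` <- function(x, i, j, ..., drop = FALSE) {
  sp <- attr(x, "source_path")
  y <- unclass(x)[i, j, drop = FALSE]
  structure(y, source_path = sp, class = "result_matrix")
}

# internal: check the object and optionally the K >= 2 entry condition
validate_rm <- function(m, need_k2 = FALSE) {
  if (!inherits(m, "result_matrix"))
    stop("expected a `result_matrix` (see result_matrix(), read_result_table())",
         call. = FALSE)
  if (need_k2 && ncol(m) < 2)
    stop("at least 2 method columns are required for comparison", call. = FALSE)
  invisible(m)
}

# internal: resolve method names to column indices with a clear error
method_index <- function(m, methods) {
  idx <- match(methods, colnames(m))
  if (anyNA(idx))
    stop("unknown method name(s): ",
         paste(methods[is.na(idx)], collapse = ", "),
         "; available: ", paste(colnames(m), collapse = ", "), call. = FALSE)
  idx
}

#' Read a markers-by-methods p-value table from TSV
#'
#' The interchange format is UTF-8, tab-separated, with a mandatory header
#' row: the first cell labels the marker column (any label is accepted) and
#' the remaining cells name the methods. Each subsequent row is a marker id
#' followed by decimal p-values (scientific notation accepted). Tokens in
#' \code{missing_tokens} become \code{NA}.
#'
#' @param path path to the TSV file.
#' @param missing_tokens character vector of cell values treated as missing.
#' @param min_methods minimum number of method columns; the default 2 is
#'   what any comparison needs, but \code{\link{merge_result_tables}} /
#'   the \code{merge} subcommand accept single-method files
#'   (\code{min_methods = 1}).
#' @return a \code{result_matrix} preserving the file's row and column order.
#' @export
read_result_table <- function(path, missing_tokens = c("NA", "", "."),
                              min_methods = 2L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, na.strings = NULL,
                           quote = "", comment.char = "",
                           fileEncoding = "UTF-8")
  if (ncol(raw) - 1 < min_methods)
    stop("need at least ", min_methods, " method columns (found ",
         ncol(raw) - 1, ") in ", path, call. = FALSE)
  ids <- raw[[1]]
  methods <- colnames(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  miss <- vals %in% missing_tokens
  dim(miss) <- dim(vals)
  parsed <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(!miss & is.na(parsed))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(vals)) + 1
    j <- ((bad[1] - 1) %/% nrow(vals)) + 1
    stop(sprintf("non-numeric cell '%s' at row %d (marker '%s'), column '%s'",
                 vals[bad[1]], i, ids[i], methods[j]), call. = FALSE)
  }
  parsed[miss] <- NA_real_
  result_matrix(parsed, marker_ids = ids, method_names = methods,
                source_path = path)
}

#' Write a result matrix to TSV
#'
#' Emits the same dialect \code{\link{read_result_table}} accepts; missing
#' entries are written as \code{"NA"}; values keep full decimal precision so
#' that a read/write round trip is exact.
#'
#' @param m a \code{result_matrix}.
#' @param path output file path.
#' @param marker_column header label for the first column.
#' @return \code{path}, invisibly.
#' @export
write_result_table <- function(m, path, marker_column = "marker") {
  validate_rm(m)
  cells <- format_pv(unclass(m))
  lines <- c(paste(c(marker_column, colnames(m)), collapse = "\t"),
             if (nrow(m)) paste(rownames(m),
                                apply(cells, 1L, paste, collapse = "\t"),
                                sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

# internal: full-precision decimal rendering, NA -> "NA"
format_pv <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 17, scientific = NA)
  }, character(1))
  dim(out) <- dim(x)
  out
}

#' Filter markers by missing-value policy
#'
#' Under \code{"drop_any_missing"} (the behaviour applied to real result
#' tables, where markers with any NA are removed before analysis) only fully
#' observed markers are kept, in their original order. Under
#' \code{"pairwise_complete"} the matrix is returned unchanged and downstream
#' pairwise operations handle missingness per method pair.
#'
#' @param m a \code{result_matrix}.
#' @param policy one of \code{"drop_any_missing"}, \code{"pairwise_complete"}.
#' @return a \code{result_matrix}; possibly with zero rows.
#' @export
filter_missing <- function(m, policy = c("drop_any_missing",
                                         "pairwise_complete")) {
  validate_rm(m)
  policy <- match.arg(policy)
  if (policy == "pairwise_complete") return(m)
  keep <- rowSums(is.na(m)) == 0L
  m[keep, , drop = FALSE]
}

#' Merge several one-or-more-method tables by marker id
#'
#' Outer join on marker id: the union of all markers is kept (first-seen
#' order); a marker absent from a file gets \code{NA} for that file's
#' methods. Supports one-file-per-method workflows.
#'
#' @param ... \code{result_matrix} objects.
#' @return a combined \code{result_matrix}.
#' @export
merge_result_tables <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1]]) &&
      !inherits(mats[[1]], "result_matrix"))
    mats <- mats[[1]]
  if (!length(mats)) stop("no tables to merge", call. = FALSE)
  lapply(mats, validate_rm)
  methods <- unlist(lapply(mats, colnames))
  if (anyDuplicated(methods))
    stop("duplicate method name(s) across tables: ",
         paste(unique(methods[duplicated(methods)]), collapse = ", "),
         call. = FALSE)
  ids <- unique(unlist(lapply(mats, rownames)))
  out <- matrix(NA_real_, length(ids), length(methods),
                dimnames = list(ids, methods))
  col0 <- 0L
  for (m in mats) {
    out[match(rownames(m), ids), col0 + seq_len(ncol(m))] <- unclass(m)
    col0 <- col0 + ncol(m)
  }
  result_matrix(out)
}

#' Floor-clamp p-values before log transforms
#'
#' \code{-log10(0)} is undefined while real analysis tools do emit exact
#' zeros, so zeros (and sub-floor values) are clamped to \code{floor} before
#' any log transform or Fisher combination.
#'
#' @param p numeric vector of p-values.
#' @param floor positive clamp value, default \code{1e-300}.
#' @return clamped vector; NA preserved.
#' @export
clamp_pvalues <- function(p, floor = 1e-300) {
  stopifnot(is.numeric(floor), length(floor) == 1L, floor > 0)
  pmax(p, floor)
}

#' Transform p-values for plotting / correlation
#'
#' @param p numeric p-values.
#' @param transform \code{"neglog10"} (default; \code{-log10} after floor
#'   clamping) or \code{"raw"}.
#' @param floor clamp passed to \code{\link{clamp_pvalues}}.
#' @return transformed numeric vector.
#' @export
transform_pvalues <- function(p, transform = c("neglog10", "raw"),
                              floor = 1e-300) {
  transform <- match.arg(transform)
  if (transform == "raw") return(p)
  -log10(clamp_pvalues(p, floor))
}
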