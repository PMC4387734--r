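#' Detect the type of a marker identifier
#'
#' Classifies an identifier so the right annotation resource can be linked:
#' dbSNP rsIDs (\code{rs} followed by digits, case-insensitive), Ensembl
#' ids (\code{ENS...G/T/P + digits}; recognised but not linkable -- web
#' annotation expects official gene symbols), plain alphanumeric ids as
#' gene symbols (array probe ids such as \code{BB471471} are
#' indistinguishable from symbols and fall in this class too), anything
#' else as unknown.
#'
#' @param id character vector of non-empty marker identifiers.
#' @return character vector with values in \code{"snp_rsid"},
#'   \code{"gene_symbol"}, \code{"ensembl_id"}, \code{"unknown"}.
#' @examples
#' detect_marker_type(c("rs1112069", "Cyyr1", "ENSG00000139618"))
#' @export
detect_marker_type <- function(id) {
  if (!is.character(id) || !length(id) || any(is.na(id)) || any(!nzchar(id)))
    stop("marker ids must be non-empty strings", call. = FALSE)
  out <- rep("unknown", length(id))
  out[grepl("^[A-Za-z0-9]+$", id)] <- "gene_symbol"
  out[grepl("^ENS[A-Z]*[GTP][0-9]+(\\.[0-9]+)?$", id)] <- "ensembl_id"
  out[grepl("^rs[0-9]+$", id, ignore.case = TRUE)] <- "snp_rsid"
  out
}

# URL templates; "{id}" is substituted. Kept in options so users can update
# them when the sites change: options(pvcomp.annotation_templates = ...).
default_annotation_templates <- list(
  ncbi_snp  = "https://www.ncbi.nlm.nih.gov/snp/{id}",
  ncbi_gene = "https://www.ncbi.nlm.nih.gov/gene/?term={id}",
  david     = "https://david.ncifcrf.gov/api.jsp?type=OFFICIAL_GENE_SYMBOL&ids={id}&tool=summary"
)

#' Annotation URL templates in effect
#'
#' @return named list of URL templates (\code{"{id}"} placeholder) for the
#'   dbSNP record page, the NCBI Gene symbol search, and the DAVID gene
#'   lookup; override via \code{options(pvcomp.annotation_templates = ...)}.
#' @export
annotation_templates <- function() {
  tpl <- getOption("pvcomp.annotation_templates", NULL)
  out <- default_annotation_templates
  if (!is.null(tpl)) out[names(tpl)] <- tpl
  out
}

#' Build an annotation URL for a marker
#'
#' Constructs (but never fetches) the web-annotation link matching the
#' marker type: rsIDs link to their dbSNP record, gene symbols to the NCBI
#' Gene search or the DAVID lookup. Ensembl ids and unrecognised ids get
#' \code{NA} (no supported web annotation).
#'
#' @param id character vector of marker ids.
#' @param target \code{"ncbi"} or \code{"david"}.
#' @return character vector of URLs, \code{NA} where no link applies.
#' @examples
#' annotation_url("rs1112069", "ncbi")
#' annotation_url("Cyyr1", "david")
#' @export
annotation_url <- function(id, target = c("ncbi", "david")) {
  target <- match.arg(target)
  type <- detect_marker_type(id)
  tpl <- annotation_templates()
  enc <- vapply(id, utils::URLencode, character(1), reserved = TRUE,
                USE.NAMES = FALSE)
  out <- rep(NA_character_, length(id))
  fill <- function(template, e) {
    vapply(e, function(x) sub("{id}", x, template, fixed = TRUE),
           character(1), USE.NAMES = FALSE)
  }
  if (target == "ncbi") {
    i <- type == "snp_rsid"
    out[i] <- fill(tpl$ncbi_snp, enc[i])
    j <- type == "gene_symbol"
    out[j] <- fill(tpl$ncbi_gene, enc[j])
  } else {
    j <- type == "gene_symbol"
    out[j] <- fill(tpl$david, enc[j])
  }
  out
}

#' Annotate all markers of a result matrix (or an id vector)
#'
#' @param ids character vector of marker ids, or a \code{result_matrix}.
#' @return data.frame with columns \code{marker}, \code{type},
#'   \code{ncbi_url}, \code{david_url}.
#' @export
annotate_markers <- function(ids) {
  if (inherits(ids, "result_matrix")) ids <- marker_ids(ids)
  data.frame(marker = ids,
             type = detect_marker_type(ids),
             ncbi_url = annotation_url(ids, "ncbi"),
             david_url = annotation_url(ids, "david"),
             stringsAsFactors = FALSE)
}
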