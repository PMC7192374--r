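## Packaged reference call tables: published subtype calls for the 17-line
## TNBC cell panel, stored long (one row per sample x condition) and split
## into one subtype_calls table per condition on load.

load_condition_calls <- function(file) {
  path <- system.file("extdata", file, package = "centrotype",
                      mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", quote = "",
                          colClasses = "character", check.names = FALSE)
  df$primary_subtype[df$primary_subtype == "UNS"] <- NA
  df$primary_rho <- suppressWarnings(as.numeric(df$primary_rho))
  df$dual_subtypes[is.na(df$dual_subtypes)] <- ""
  conditions <- unique(df$condition)
  out <- lapply(conditions, function(cc)
    subtype_calls(df[df$condition == cc, call_columns]))
  stats::setNames(out, conditions)
}

#' Reference subtype calls for the 17-cell-line TNBC panel
#'
#' Published calls for 17 TNBC cell lines under two centroid classifiers
#' (the 2188-gene TNBCtype and 101-gene TNBCtype-IM algorithms) and two
#' growth conditions (in vitro culture and xenograft tumors). These calls
#' are fixture inputs for the concordance and stability analyses; the
#' underlying expression data and centroid tables are external and not
#' redistributed.
#'
#' @return named list of four \code{\link{subtype_calls}} tables:
#'   \code{tnbctype_invitro}, \code{tnbctypeim_invitro},
#'   \code{tnbctype_xeno}, \code{tnbctypeim_xeno}.
#' @export
tnbc_cell_line_calls <- function() {
  load_condition_calls("tnbc_cell_line_calls.tsv")
}

#' Reference subtype calls for the six stable lines across five sources
#'
#' Published calls for the six molecularly stable TNBC cell lines
#' re-derived from five independent expression sources (GSE15361, GSE10890,
#' CCLE, xenograft RNA-seq, and the original 2188-gene classification).
#' Lines absent from a source carry no row for that condition.
#'
#' @return named list of five \code{\link{subtype_calls}} tables keyed by
#'   source.
#' @export
tnbc_stable_line_calls <- function() {
  load_condition_calls("tnbc_stable_line_calls.tsv")
}
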