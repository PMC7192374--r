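#' Read a gene-by-sample expression matrix from CSV/TSV
#'
#' Expects a header row of sample IDs and a first column of gene IDs; all
#' remaining cells must be numeric. Lines starting with \code{#} are ignored.
#'
#' @param path file path.
#' @param delimiter field separator, \code{"\t"} (default) or \code{","}.
#' @param scale declared measurement scale of the values
#'   (\code{"linear"}, \code{"log2"} or \code{"log2_centered"}).
#' @param batch optional per-sample batch labels (recycled name order must
#'   match the file's sample columns).
#' @return an \code{\link{expression_matrix}}.
#' @export
read_expression_matrix <- function(path, delimiter = "\t",
                                   scale = c("linear", "log2", "log2_centered"),
                                   batch = NULL) {
  scale <- match.arg(scale)
  raw <- read_table_checked(path, delimiter)
  gid <- raw[[1]]
  if (anyDuplicated(gid))
    stop("duplicate gene ID(s): ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  vals <- as_numeric_cells(raw[-1], path)
  rownames(vals) <- gid
  expression_matrix(vals, scale = scale, batch = batch)
}

#' Write an expression matrix to CSV/TSV
#'
#' Values are written at 6 significant digits; \code{read_expression_matrix}
#' on the result recovers the matrix at that precision.
#'
#' @param x an \code{expr_matrix}.
#' @param path output file path.
#' @param delimiter field separator, tab by default.
#' @return invisibly, \code{path}.
#' @export
write_expression_matrix <- function(x, path, delimiter = "\t") {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x),
                   apply(unclass(x), 2, format_num),
                   check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a centroid set from TSV
#'
#' Header row names the subtypes; a final column named \code{IM} (if present)
#' is interpreted as the immunomodulatory overlay centroid rather than a
#' subtype; first column holds gene IDs.
#'
#' @param path file path.
#' @param delimiter field separator, tab by default.
#' @param algorithm optional signature label stored on the result.
#' @return a \code{\link{centroid_set}}.
#' @export
read_centroid_set <- function(path, delimiter = "\t", algorithm = "") {
  raw <- read_table_checked(path, delimiter)
  gid <- raw[[1]]
  vals <- as_numeric_cells(raw[-1], path)
  rownames(vals) <- gid
  im <- NULL
  if ("IM" %in% colnames(vals)) {
    im <- vals[, "IM"]
    vals <- vals[, setdiff(colnames(vals), "IM"), drop = FALSE]
  }
  centroid_set(vals, im_centroid = im, algorithm = algorithm)
}

#' Write a centroid set to TSV
#'
#' @param x a \code{centroid_set}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_centroid_set <- function(x, path) {
  stopifnot(inherits(x, "centroid_set"))
  vals <- x$values
  if (!is.null(x$im_centroid)) vals <- cbind(vals, IM = x$im_centroid)
  df <- data.frame(gene_id = rownames(vals), apply(vals, 2, format_num),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse transcript-level FPKM to gene level
#'
#' Transcript FPKM values are summed into one value per gene and sample, the
#' standard aggregation when a transcript quantifier reports per-isoform
#' abundances.
#'
#' @param transcript_table data.frame with columns \code{gene_id},
#'   \code{transcript_id}, then one numeric FPKM column per sample.
#' @return a linear-scale \code{\link{expression_matrix}}, one row per
#'   distinct gene (in first-appearance order).
#' @export
sum_transcript_fpkm <- function(transcript_table) {
  df <- as.data.frame(transcript_table)
  need <- c("gene_id", "transcript_id")
  if (!all(need %in% names(df)))
    stop("transcript table needs columns gene_id, transcript_id", call. = FALSE)
  value_cols <- setdiff(names(df), need)
  if (!length(value_cols))
    stop("transcript table has no sample FPKM columns", call. = FALSE)
  vals <- as.matrix(df[value_cols])
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("FPKM values must be finite numbers", call. = FALSE)
  if (any(vals < 0))
    stop("negative FPKM value(s) found; FPKM must be >= 0", call. = FALSE)
  gene_order <- unique(as.character(df$gene_id))
  summed <- rowsum(vals, group = as.character(df$gene_id), reorder = FALSE)
  summed <- summed[gene_order, , drop = FALSE]
  expression_matrix(summed, scale = "linear")
}

#' Check signature-gene coverage of an expression matrix
#'
#' Reports the fraction of centroid (signature) genes absent from the
#' matrix. Classification must be refused when that fraction strictly
#' exceeds \code{max_missing}: a matrix missing more than 10\% of signature
#' genes cannot be scored reliably, which is the standard gate before
#' centroid correlation. The comparison is strict, so a matrix missing
#' exactly 10\% of genes passes.
#'
#' @param x an \code{expr_matrix}.
#' @param centroids a \code{centroid_set}.
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @return object of class \code{coverage_report}: counts, missing fraction,
#'   missing gene IDs, and logical \code{ok}.
#' @export
check_gene_coverage <- function(x, centroids, max_missing = 0.10) {
  stopifnot(inherits(x, "expr_matrix"), inherits(centroids, "centroid_set"))
  if (!is.numeric(max_missing) || max_missing < 0 || max_missing > 1)
    stop("`max_missing` must be in [0, 1]", call. = FALSE)
  sig <- rownames(centroids$values)
  if (!length(sig))
    stop("centroid set has no genes", call. = FALSE)
  missing <- setdiff(sig, rownames(x))
  frac <- length(missing) / length(sig)
  structure(list(n_signature_genes = length(sig),
                 n_present = length(sig) - length(missing),
                 missing_fraction = frac,
                 missing_gene_ids = sort(missing),
                 max_missing = max_missing,
                 ok = frac <= max_missing),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %d/%d signature genes present (%.1f%% missing): %s\n",
              x$n_present, x$n_signature_genes, 100 * x$missing_fraction,
              if (x$ok) "PASS" else sprintf("FAIL (> %.0f%% missing)",
                                            100 * x$max_missing)))
  invisible(x)
}

#' Write subtype calls to TSV
#'
#' One header line, then one row per sample with its status, primary subtype
#' (\code{UNS} for unstable), primary correlation, ranked dual subtypes as
#' semicolon-joined \code{name:rho} pairs, and IM status. Numeric values are
#' written at 6 significant digits. \code{\link{read_calls}} inverts this
#' serialization exactly; the per-subtype correlation matrix attached by
#' \code{\link{classify_cohort}} is metadata and is not serialized.
#'
#' @param calls a \code{subtype_calls} table.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_calls <- function(calls, path) {
  calls <- subtype_calls(calls)
  if (!nrow(calls))
    stop("refusing to write an empty call table", call. = FALSE)
  out <- calls
  out$primary_subtype[out$status == "unstable"] <- "UNS"
  out$primary_rho <- format_num(out$primary_rho)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read subtype calls from TSV
#'
#' @param path file path written by \code{\link{write_calls}} (or shaped the
#'   same way). Lines starting with \code{#} are ignored.
#' @return a \code{subtype_calls} table.
#' @export
read_calls <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", quote = "",
                          colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(call_columns, names(df))
  if (length(missing_cols))
    stop("call file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$primary_subtype[df$primary_subtype == "UNS"] <- NA
  df$primary_rho <- suppressWarnings(as.numeric(df$primary_rho))
  df$dual_subtypes[is.na(df$dual_subtypes)] <- ""
  subtype_calls(df)
}

## Shared low-level reader: header + first-column IDs, comment lines allowed.
read_table_checked <- function(path, delimiter) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, sep = delimiter, header = TRUE,
                      comment.char = "#", quote = "", check.names = FALSE,
                      colClasses = "character"),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (!nrow(df) || ncol(df) < 2)
    stop("malformed table ", path,
         ": need a header row plus at least one ID and one value column",
         call. = FALSE)
  if (anyDuplicated(colnames(df)))
    stop("malformed header in ", path, ": duplicate column names",
         call. = FALSE)
  df
}

## Convert character cells to numeric, reporting the first offending cell.
as_numeric_cells <- function(df, path) {
  vals <- matrix(NA_real_, nrow(df), ncol(df),
                 dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & df[[j]] != "NA")
    if (length(bad))
      stop(sprintf("non-numeric value %s in %s (row %d, column %s)",
                   dQuote(df[[j]][bad[1]]), path, bad[1], names(df)[j]),
           call. = FALSE)
    vals[, j] <- v
  }
  if (anyNA(vals))
    stop("missing value(s) in ", path, call. = FALSE)
  vals
}
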