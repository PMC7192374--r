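#' Construct an expression matrix
#'
#' A gene-by-sample numeric matrix carrying its measurement scale and an
#' optional per-sample batch label. Linear-scale values (FPKM/RPKM, array
#' intensities) must be non-negative; \code{log2} and \code{log2_centered}
#' values are unrestricted reals.
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample IDs).
#' @param scale one of \code{"linear"}, \code{"log2"}, \code{"log2_centered"}.
#' @param batch optional character vector of batch labels, one per sample.
#' @return an object of class \code{expr_matrix} (a numeric matrix with
#'   \code{scale} and \code{batch} attributes).
#' @export
expression_matrix <- function(values,
                              scale = c("linear", "log2", "log2_centered"),
                              batch = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || anyNA(gid) || !length(gid))
    stop("gene IDs (rownames) must be present and non-empty", call. = FALSE)
  if (is.null(sid) || anyNA(sid) || !length(sid))
    stop("sample IDs (colnames) must be present and non-empty", call. = FALSE)
  if (anyDuplicated(gid))
    stop("duplicate gene ID(s): ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample ID(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  if (any(!is.finite(values)))
    stop("all expression values must be finite", call. = FALSE)
  if (scale == "linear" && any(values < 0))
    stop("linear-scale expression values must be >= 0", call. = FALSE)
  if (!is.null(batch)) {
    batch <- as.character(batch)
    if (length(batch) != ncol(values))
      stop("`batch` must have one label per sample", call. = FALSE)
  }
  structure(values, scale = scale, batch = batch,
            class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s%s\n",
              nrow(x), ncol(x), attr(x, "scale"),
              if (is.null(attr(x, "batch"))) ""
              else sprintf(", %d batch(es)",
                           length(unique(attr(x, "batch"))))))
  invisible(x)
}

#' Measurement scale of an expression matrix
#' @param x an \code{expr_matrix}.
#' @return scale string.
#' @export
expr_scale <- function(x) attr(x, "scale")

#' Batch labels of an expression matrix
#' @param x an \code{expr_matrix}.
#' @return character vector of per-sample batch labels, or NULL.
#' @export
expr_batch <- function(x) attr(x, "batch")

#' Construct a centroid set
#'
#' Per-gene reference expression profiles, one column per molecular subtype,
#' on the same centered-log2 scale the classifier consumes. May carry an
#' additional immunomodulatory (IM) overlay centroid over the same genes.
#'
#' @param values numeric matrix, genes in rows, subtypes in columns.
#' @param im_centroid optional numeric vector, one value per gene, the IM
#'   overlay centroid.
#' @param algorithm free-text label for the signature (e.g. "101-gene").
#' @return object of class \code{centroid_set}.
#' @export
centroid_set <- function(values, im_centroid = NULL, algorithm = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  gid <- rownames(values)
  sub <- colnames(values)
  if (is.null(gid) || anyDuplicated(gid))
    stop("centroid gene IDs must be present and unique", call. = FALSE)
  if (is.null(sub) || anyDuplicated(sub))
    stop("subtype names must be present and unique", call. = FALSE)
  if (ncol(values) < 2)
    stop("a centroid set needs at least 2 subtypes", call. = FALSE)
  if (any(!is.finite(values)))
    stop("all centroid values must be finite", call. = FALSE)
  if (!is.null(im_centroid)) {
    im_centroid <- as.numeric(im_centroid)
    if (length(im_centroid) != nrow(values) || any(!is.finite(im_centroid)))
      stop("`im_centroid` must be one finite value per gene", call. = FALSE)
    names(im_centroid) <- gid
  }
  structure(list(values = values, im_centroid = im_centroid,
                 algorithm = as.character(algorithm)[1]),
            class = "centroid_set")
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf("<centroid_set%s> %d genes, subtypes: %s%s\n",
              if (nzchar(x$algorithm)) paste0(" ", x$algorithm) else "",
              nrow(x$values), paste(colnames(x$values), collapse = ", "),
              if (is.null(x$im_centroid)) "" else " (+ IM overlay)"))
  invisible(x)
}

#' Subtype names of a centroid set
#' @param x a \code{centroid_set}.
#' @return character vector of subtype names.
#' @export
subtype_names <- function(x) colnames(x$values)

## Canonical column schema for a table of subtype calls.
call_columns <- c("sample_id", "status", "primary_subtype", "primary_rho",
                  "dual_subtypes", "im_status")

#' Construct a table of subtype calls
#'
#' One row per sample: final status (\code{single}, \code{dual} or
#' \code{unstable}), the primary subtype and its Spearman rho (NA for
#' unstable), ranked secondary (dual) subtypes serialized as
#' semicolon-joined \code{name:rho} pairs, and IM status
#' (\code{positive}, \code{negative} or \code{undetermined}).
#'
#' @param df data.frame with columns \code{sample_id}, \code{status},
#'   \code{primary_subtype}, \code{primary_rho}, \code{dual_subtypes},
#'   \code{im_status}.
#' @return object of class \code{subtype_calls} (a data.frame).
#' @export
subtype_calls <- function(df) {
  missing_cols <- setdiff(call_columns, names(df))
  if (length(missing_cols))
    stop("missing call column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[, call_columns]
  df$sample_id <- as.character(df$sample_id)
  df$status <- as.character(df$status)
  df$primary_subtype <- as.character(df$primary_subtype)
  df$primary_rho <- as.numeric(df$primary_rho)
  df$dual_subtypes <- as.character(df$dual_subtypes)
  df$im_status <- as.character(df$im_status)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ID(s) in call table", call. = FALSE)
  bad <- !df$status %in% c("single", "dual", "unstable")
  if (any(bad))
    stop("invalid status value(s): ",
         paste(unique(df$status[bad]), collapse = ", "), call. = FALSE)
  bad_im <- !df$im_status %in% c("positive", "negative", "undetermined")
  if (any(bad_im))
    stop("invalid im_status value(s): ",
         paste(unique(df$im_status[bad_im]), collapse = ", "), call. = FALSE)
  uns <- df$status == "unstable"
  if (any(!is.na(df$primary_subtype[uns])) || any(is.na(df$primary_subtype[!uns])))
    stop("primary_subtype must be NA exactly for unstable calls", call. = FALSE)
  if (any(df$status == "dual" & !nzchar(df$dual_subtypes)))
    stop("dual calls must list their secondary subtype(s)", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("subtype_calls", "data.frame")
  df
}

#' @export
print.subtype_calls <- function(x, ...) {
  cat(sprintf("<subtype_calls> %d samples (%d single, %d dual, %d unstable)\n",
              nrow(x), sum(x$status == "single"), sum(x$status == "dual"),
              sum(x$status == "unstable")))
  print.data.frame(x, ...)
  invisible(x)
}

## Serialize / parse the ranked dual-subtype list ("name:rho;name:rho").
serialize_duals <- function(names, rhos) {
  if (!length(names)) return("")
  paste(sprintf("%s:%s", names, format_num(rhos)), collapse = ";")
}

parse_duals <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(subtype = character(), rho = numeric()))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("malformed dual-subtype field: ", s, call. = FALSE)
  data.frame(subtype = vapply(parts, `[`, "", 1),
             rho = as.numeric(vapply(parts, `[`, "", 2)))
}

## 6 significant digits, no scientific notation: the package's text precision.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(signif(v, 6), scientific = FALSE, trim = TRUE)
  }, "")
  out
}
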