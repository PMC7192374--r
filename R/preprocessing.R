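#' Preprocessing configuration
#'
#' @param pseudocount non-negative value added before log2 (default 1.0);
#'   must be > 0 when the matrix contains zeros.
#' @param centering_statistic per-gene statistic subtracted within each
#'   batch, \code{"mean"} (default) or \code{"median"}.
#' @return object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(pseudocount = 1.0,
                              centering_statistic = c("mean", "median")) {
  centering_statistic <- match.arg(centering_statistic)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0)
    stop("`pseudocount` must be a single non-negative number", call. = FALSE)
  structure(list(pseudocount = pseudocount,
                 centering_statistic = centering_statistic),
            class = "preprocess_config")
}

#' Log2-transform a linear-scale expression matrix
#'
#' Each value v becomes log2(v + pseudocount). Monotone per entry, so
#' within-sample gene ranks are preserved — the property the downstream
#' rank-correlation classifier relies on.
#'
#' @param x a linear-scale \code{expr_matrix}.
#' @param config a \code{\link{preprocess_config}}.
#' @return an \code{expr_matrix} with scale \code{"log2"}.
#' @export
log2_transform <- function(x, config = preprocess_config()) {
  stopifnot(inherits(x, "expr_matrix"), inherits(config, "preprocess_config"))
  if (expr_scale(x) != "linear")
    stop("matrix is already on the ", expr_scale(x),
         " scale; log2_transform expects linear values", call. = FALSE)
  if (config$pseudocount == 0 && any(x == 0))
    stop("zero expression value with pseudocount 0: log2 undefined; ",
         "use a positive pseudocount", call. = FALSE)
  vals <- log2(unclass(x) + config$pseudocount)
  expression_matrix(vals, scale = "log2", batch = expr_batch(x))
}

#' Center each gene within its batch
#'
#' Subtracts the per-gene centering statistic (mean by default) within each
#' batch, yielding the centered representation the centroid classifier
#' consumes. With no batch labels the whole matrix is one batch. A
#' single-sample batch centers to all zeros — the sample becomes
#' uninformative and will classify as unstable — so a warning is raised.
#'
#' @param x an \code{expr_matrix} on the \code{"log2"} scale.
#' @param batch optional per-sample batch labels; defaults to the matrix's
#'   own \code{batch} attribute, else a single batch.
#' @param config a \code{\link{preprocess_config}}.
#' @return an \code{expr_matrix} with scale \code{"log2_centered"}.
#' @export
center_genes <- function(x, batch = NULL, config = preprocess_config()) {
  stopifnot(inherits(x, "expr_matrix"), inherits(config, "preprocess_config"))
  if (expr_scale(x) == "linear")
    stop("center_genes expects log2-scale values; run log2_transform first",
         call. = FALSE)
  if (is.null(batch)) batch <- expr_batch(x)
  if (is.null(batch)) batch <- rep("all", ncol(x))
  batch <- as.character(batch)
  if (length(batch) != ncol(x))
    stop("`batch` must have one label per sample", call. = FALSE)
  if (anyNA(batch))
    stop("unknown (NA) batch label", call. = FALSE)
  vals <- unclass(x)
  stat_fun <- switch(config$centering_statistic,
                     mean = rowMeans,
                     median = function(m) apply(m, 1, stats::median))
  for (b in unique(batch)) {
    idx <- which(batch == b)
    if (length(idx) == 1)
      warning("batch ", dQuote(b), " has a single sample; centering zeroes ",
              "its profile and it will classify as unstable", call. = FALSE)
    vals[, idx] <- vals[, idx, drop = FALSE] -
      stat_fun(vals[, idx, drop = FALSE])
  }
  expression_matrix(vals, scale = "log2_centered", batch = batch)
}

#' Run the full preprocessing chain
#'
#' Applies whatever transforms the declared scale still needs: linear
#' matrices are log2-transformed then batch-centered; log2 matrices are
#' centered; centered matrices pass through unchanged.
#'
#' @param x an \code{expr_matrix} on any scale.
#' @param batch optional per-sample batch labels (see
#'   \code{\link{center_genes}}).
#' @param config a \code{\link{preprocess_config}}.
#' @return an \code{expr_matrix} with scale \code{"log2_centered"}.
#' @export
preprocess <- function(x, batch = NULL, config = preprocess_config()) {
  stopifnot(inherits(x, "expr_matrix"))
  if (expr_scale(x) == "linear") x <- log2_transform(x, config)
  if (expr_scale(x) == "log2") x <- center_genes(x, batch = batch,
                                                 config = config)
  x
}
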