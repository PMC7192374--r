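#' Train a nearest-shrunken-centroids model
#'
#' Standard soft-thresholding formulation: for gene i and class k the
#' standardized deviation is d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0)),
#' with pooled within-class standard deviation s_i, stabilizer s0 = median
#' of the s_i, and m_k = sqrt(1/n_k - 1/n). Shrinkage replaces d_ik by
#' sign(d_ik) * max(|d_ik| - delta, 0) and reconstructs the class centroid
#' as xbar_i + m_k * (s_i + s0) * d'_ik. Genes with at least one nonzero
#' shrunken deviation form the reduced signature. At delta = 0 the shrunken
#' centroids equal the raw class means.
#'
#' @param x an \code{expr_matrix} on the \code{"log2_centered"} scale (any
#'   scale is accepted; values are used as-is).
#' @param labels per-sample class (subtype) labels.
#' @param delta non-negative shrinkage threshold.
#' @return object of class \code{shrunken_model}: \code{overall_centroid},
#'   raw and shrunken \code{class_centroids}, \code{delta},
#'   \code{selected_genes}, \code{per_gene_s}, \code{s0}, class sizes.
#' @export
train_shrunken_centroids <- function(x, labels, delta = 0) {
  stopifnot(inherits(x, "expr_matrix"))
  labels <- as.character(labels)
  if (length(labels) != ncol(x))
    stop("`labels` must have one entry per sample", call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0)
    stop("`delta` must be a single non-negative number", call. = FALSE)
  n_k <- table(labels)
  if (length(n_k) < 2)
    stop("need at least 2 classes", call. = FALSE)
  if (any(n_k < 2))
    stop("class(es) with < 2 samples: ",
         paste(names(n_k)[n_k < 2], collapse = ", "), call. = FALSE)
  vals <- unclass(x)
  n <- ncol(vals)
  classes <- names(n_k)
  overall <- rowMeans(vals)
  class_means <- matrix(
    vapply(classes, function(k)
      rowMeans(vals[, labels == k, drop = FALSE]), numeric(nrow(vals))),
    nrow = nrow(vals), dimnames = list(rownames(vals), classes))
  # pooled within-class sd: sum of squared deviations from class means
  ss <- rowSums(matrix(vapply(classes, function(k) {
    m <- vals[, labels == k, drop = FALSE]
    rowSums((m - class_means[, k])^2)
  }, numeric(nrow(vals))), nrow = nrow(vals)))
  s <- sqrt(ss / (n - length(classes)))
  s0 <- stats::median(s)
  m_k <- sqrt(1 / as.numeric(n_k[classes]) - 1 / n)
  names(m_k) <- classes
  d <- sweep(class_means - overall, 1, s + s0, "/")
  d <- sweep(d, 2, m_k, "/")
  d_shrunk <- sign(d) * pmax(abs(d) - delta, 0)
  # reconstruct as class mean minus the clipped deviation so delta = 0 is
  # the exact identity on the raw class means
  clipped <- sign(d) * pmin(abs(d), delta)
  shrunk <- class_means - sweep(sweep(clipped, 2, m_k, "*"), 1, s + s0, "*")
  selected <- rownames(vals)[rowSums(abs(d_shrunk) > 0) > 0]
  structure(list(overall_centroid = overall,
                 class_centroids = shrunk,
                 raw_class_means = class_means,
                 delta = delta,
                 selected_genes = selected,
                 per_gene_s = s, s0 = s0, m_k = m_k,
                 n_per_class = as.numeric(n_k[classes]),
                 classes = classes),
            class = "shrunken_model")
}

#' @export
print.shrunken_model <- function(x, ...) {
  cat(sprintf(
    "<shrunken_model> %d classes, delta = %g, %d/%d genes selected\n",
    length(x$classes), x$delta, length(x$selected_genes),
    length(x$overall_centroid)))
  invisible(x)
}

#' Classify samples with a shrunken-centroid discriminant score
#'
#' Assigns each sample the class minimizing the (prior-free) discriminant
#' sum over genes of (x_i - xbar'_ik)^2 / (s_i + s0)^2. Used inside
#' cross-validation; the exported reduced centroid set is deployed through
#' the Spearman classifier instead.
#'
#' @param model a \code{shrunken_model}.
#' @param x an \code{expr_matrix} over the training genes.
#' @return character vector of predicted class labels, one per sample.
#' @export
predict_shrunken <- function(model, x) {
  stopifnot(inherits(model, "shrunken_model"), inherits(x, "expr_matrix"))
  genes <- names(model$overall_centroid)
  if (!all(genes %in% rownames(x)))
    stop("matrix lacks training gene(s)", call. = FALSE)
  vals <- unclass(x)[genes, , drop = FALSE]
  w <- (model$per_gene_s + model$s0)^2
  scores <- vapply(model$classes, function(k) {
    colSums((vals - model$class_centroids[, k])^2 / w)
  }, numeric(ncol(vals)))
  scores <- matrix(scores, ncol = length(model$classes),
                   dimnames = list(colnames(vals), model$classes))
  model$classes[apply(scores, 1, which.min)]
}

#' Choose the shrinkage threshold by cross-validation
#'
#' Stratified K-fold cross-validation over a delta grid, minimizing the
#' misclassification count; ties are broken toward the largest delta (the
#' smallest signature), the usual parsimony rule.
#'
#' @param x an \code{expr_matrix}.
#' @param labels per-sample class labels.
#' @param delta_grid numeric vector of candidate thresholds.
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @return the selected delta, with attribute \code{cv_errors} (named
#'   misclassification counts per grid value).
#' @export
choose_delta <- function(x, labels, delta_grid, n_folds = 5, seed) {
  stopifnot(inherits(x, "expr_matrix"))
  labels <- as.character(labels)
  if (!length(delta_grid))
    stop("`delta_grid` must be non-empty", call. = FALSE)
  if (n_folds < 2)
    stop("`n_folds` must be >= 2", call. = FALSE)
  if (missing(seed))
    stop("`seed` is required for reproducible fold assignment",
         call. = FALSE)
  delta_grid <- sort(as.numeric(delta_grid))
  n_k <- table(labels)
  if (n_folds > min(n_k))
    stop("stratification error: class ", dQuote(names(n_k)[which.min(n_k)]),
         " has fewer samples than folds, so some fold loses a class ",
         "entirely", call. = FALSE)
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (k in unique(labels)) {
    idx <- sample(which(labels == k))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  errors <- stats::setNames(numeric(length(delta_grid)),
                            format(delta_grid))
  for (f in seq_len(n_folds)) {
    train <- fold != f
    if (length(unique(labels[train])) < length(unique(labels)))
      stop("fold ", f, " loses a class entirely; use fewer folds ",
           "or more samples per class", call. = FALSE)
    tr <- expression_matrix(unclass(x)[, train, drop = FALSE],
                            scale = expr_scale(x))
    te <- expression_matrix(unclass(x)[, !train, drop = FALSE],
                            scale = expr_scale(x))
    for (i in seq_along(delta_grid)) {
      model <- train_shrunken_centroids(tr, labels[train], delta_grid[i])
      pred <- predict_shrunken(model, te)
      errors[i] <- errors[i] + sum(pred != labels[!train])
    }
  }
  # ties toward the larger delta: last index of the minimum
  best <- max(which(errors == min(errors)))
  structure(delta_grid[best], cv_errors = errors)
}

#' Export a reduced centroid set from a shrunken model
#'
#' Restricts the shrunken class centroids to the selected genes, yielding a
#' \code{centroid_set} directly consumable by the Spearman classifier. This
#' deliberate hybrid — signature derived by shrinkage, deployed via rank
#' correlation — mirrors how reduced TNBC signatures are built and then
#' applied.
#'
#' @param model a \code{shrunken_model}.
#' @param algorithm label stored on the centroid set (default names the
#'   signature size).
#' @param im_centroid optional IM overlay vector over the selected genes.
#' @return a \code{\link{centroid_set}} over \code{model$selected_genes}.
#' @export
export_centroids <- function(model, algorithm = NULL, im_centroid = NULL) {
  stopifnot(inherits(model, "shrunken_model"))
  if (!length(model$selected_genes))
    stop("no genes selected at delta = ", model$delta,
         "; lower delta to retain a signature", call. = FALSE)
  vals <- model$class_centroids[model$selected_genes, , drop = FALSE]
  if (is.null(algorithm))
    algorithm <- sprintf("%d-gene shrunken", nrow(vals))
  centroid_set(vals, im_centroid = im_centroid, algorithm = algorithm)
}
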