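#' Classifier configuration
#'
#' Tuning knobs of the subtype decision procedure. The correlation cutoff of
#' 0.1 is the published operating point shared by the 2188-gene and 101-gene
#' TNBC classifiers; a subtype is a candidate only when its Spearman rho
#' strictly exceeds it.
#'
#' @param cutoff minimum Spearman rho for a subtype candidate (default 0.1,
#'   strict inequality).
#' @param alpha two-sided significance level for the correlation-difference
#'   z test that separates a predominant subtype from a dual call
#'   (default 0.05).
#' @param tie_test \code{"fisher_z"} (default): independent Fisher
#'   z-transformation test with the 1.06/(n-3) rank-correlation variance
#'   adjustment; \code{"steiger"}: dependent-correlation variant for the two
#'   rhos sharing the same sample profile.
#' @param im_cutoff Spearman rho above which the IM overlay is called
#'   positive (default 0.1, strict).
#' @return object of class \code{classifier_config}.
#' @export
classifier_config <- function(cutoff = 0.1, alpha = 0.05,
                              tie_test = c("fisher_z", "steiger"),
                              im_cutoff = 0.1) {
  tie_test <- match.arg(tie_test)
  if (!is.numeric(cutoff) || length(cutoff) != 1 ||
      cutoff <= -1 || cutoff >= 1)
    stop("`cutoff` must be a single number in (-1, 1)", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (!is.numeric(im_cutoff) || length(im_cutoff) != 1 ||
      im_cutoff <= -1 || im_cutoff >= 1)
    stop("`im_cutoff` must be in (-1, 1)", call. = FALSE)
  structure(list(cutoff = cutoff, alpha = alpha, tie_test = tie_test,
                 im_cutoff = im_cutoff),
            class = "classifier_config")
}

#' Spearman-correlate a sample profile to every subtype centroid
#'
#' Rho is computed over the genes common to the profile and the centroid
#' set, with average ranks for ties. A zero-variance profile (all genes
#' equal, e.g. a single-sample batch centered to zeros) has no defined rank
#' correlation; it is flagged with a warning and all rhos are set to NA,
#' which downstream counts as below any cutoff (the sample becomes
#' unstable).
#'
#' @param profile named numeric vector, one centered log2 value per gene.
#' @param centroids a \code{centroid_set}.
#' @return object of class \code{correlation_vector}: named \code{rho} per
#'   subtype, \code{n_genes_used}, and \code{zero_variance} flag.
#' @export
correlate_to_centroids <- function(profile, centroids) {
  stopifnot(inherits(centroids, "centroid_set"))
  if (is.null(names(profile)))
    stop("`profile` must be a named vector (names = gene IDs)", call. = FALSE)
  shared <- intersect(names(profile), rownames(centroids$values))
  if (length(shared) < 3)
    stop("only ", length(shared),
         " gene(s) shared with the centroid set; need at least 3",
         call. = FALSE)
  x <- profile[shared]
  cen <- centroids$values[shared, , drop = FALSE]
  zero_var <- stats::sd(x) == 0
  if (zero_var) {
    warning("sample profile has zero variance; rank correlation undefined, ",
            "treating every rho as below cutoff", call. = FALSE)
    rho <- stats::setNames(rep(NA_real_, ncol(cen)), colnames(cen))
  } else {
    rho <- drop(stats::cor(x, cen, method = "spearman"))
    names(rho) <- colnames(cen)
  }
  structure(list(rho = rho, n_genes_used = length(shared),
                 zero_variance = zero_var),
            class = "correlation_vector")
}

#' @export
print.correlation_vector <- function(x, ...) {
  cat(sprintf("<correlation_vector> n_genes_used = %d\n", x$n_genes_used))
  print(round(x$rho, 4))
  invisible(x)
}

#' Test whether two centroid correlations differ significantly
#'
#' The z-score method separating a predominant subtype from a dual call.
#' Default: Fisher z-transformation of each rho, difference divided by
#' sqrt(2 * 1.06/(n-3)) — the 1.06 factor is the Fieller correction for the
#' larger sampling variance of the Spearman coefficient. The
#' \code{"steiger"} variant accounts for the two correlations sharing the
#' same sample profile via the correlation between the two centroids
#' (\code{rho_ab}).
#'
#' @param rho_a,rho_b the two Spearman correlations.
#' @param n_genes number of genes both correlations were computed over
#'   (must be >= 4).
#' @param config a \code{\link{classifier_config}}.
#' @param rho_ab correlation between the two centroid profiles, used only by
#'   the Steiger variant (default 0).
#' @return list: \code{z_statistic}, \code{p_value}, logical
#'   \code{significant}.
#' @export
test_correlation_difference <- function(rho_a, rho_b, n_genes,
                                        config = classifier_config(),
                                        rho_ab = 0) {
  stopifnot(inherits(config, "classifier_config"))
  if (!is.numeric(n_genes) || n_genes < 4)
    stop("`n_genes` must be >= 4 (Fisher variance needs n - 3 > 0)",
         call. = FALSE)
  clip <- function(r) {
    if (abs(r) >= 1) {
      warning("|rho| = 1 clipped to 1 - 1e-7 before the z transform",
              call. = FALSE)
      r <- sign(r) * (1 - 1e-7)
    }
    r
  }
  rho_a <- clip(rho_a); rho_b <- clip(rho_b)
  za <- atanh(rho_a); zb <- atanh(rho_b)
  if (config$tie_test == "fisher_z") {
    z <- (za - zb) / sqrt(2 * 1.06 / (n_genes - 3))
  } else {
    rbar <- (rho_a + rho_b) / 2
    f <- min(1, (1 - rho_ab) / (2 * (1 - rbar^2)))
    h <- (1 - f * rbar^2) / (1 - rbar^2)
    z <- (za - zb) * sqrt((n_genes - 3) / (2 * (1 - rho_ab) * h))
  }
  p <- 2 * stats::pnorm(-abs(z))
  list(z_statistic = z, p_value = p, significant = p < config$alpha)
}

#' Call a subtype from a correlation vector
#'
#' The full decision tree: subtypes with rho strictly above the cutoff are
#' candidates. No candidate: unstable (UNS). One candidate: single call.
#' Several: the top candidate is z-tested against each other candidate; if
#' every other candidate is significantly lower the top subtype is
#' predominant (single call), otherwise the call is dual and all
#' non-significantly-different candidates are reported ranked by decreasing
#' rho. Exact rho ties are ordered alphabetically for determinism (a zero z
#' is never significant, so tied top candidates always yield a dual call).
#'
#' @param correlations a \code{correlation_vector}.
#' @param config a \code{\link{classifier_config}}.
#' @param sample_id identifier recorded on the call.
#' @param im_status IM overlay status to record (from
#'   \code{\link{assess_im_status}}); default \code{"undetermined"}.
#' @return object of class \code{subtype_call}: sample_id, status,
#'   primary_subtype, primary_rho, ranked \code{dual} data.frame,
#'   \code{candidates_above_cutoff}, im_status, and the input correlations.
#' @export
call_subtype <- function(correlations, config = classifier_config(),
                         sample_id = "sample", im_status = "undetermined") {
  stopifnot(inherits(correlations, "correlation_vector"),
            inherits(config, "classifier_config"))
  rho <- correlations$rho
  cand <- rho[!is.na(rho) & rho > config$cutoff]
  # decreasing rho, alphabetical among exact ties
  cand <- cand[order(-cand, names(cand))]
  empty_dual <- data.frame(subtype = character(), rho = numeric())
  if (!length(cand)) {
    out <- list(sample_id = sample_id, status = "unstable",
                primary_subtype = NA_character_, primary_rho = NA_real_,
                dual = empty_dual,
                candidates_above_cutoff = character(),
                im_status = im_status, correlations = correlations)
  } else if (length(cand) == 1) {
    out <- list(sample_id = sample_id, status = "single",
                primary_subtype = names(cand), primary_rho = cand[[1]],
                dual = empty_dual,
                candidates_above_cutoff = names(cand),
                im_status = im_status, correlations = correlations)
  } else {
    n <- correlations$n_genes_used
    keep <- vapply(seq_along(cand)[-1], function(i) {
      !test_correlation_difference(cand[[1]], cand[[i]], n,
                                   config)$significant
    }, logical(1))
    if (any(keep)) {
      dual <- data.frame(subtype = names(cand)[-1][keep],
                         rho = unname(cand[-1][keep]))
      out <- list(sample_id = sample_id, status = "dual",
                  primary_subtype = names(cand)[1], primary_rho = cand[[1]],
                  dual = dual,
                  candidates_above_cutoff = names(cand),
                  im_status = im_status, correlations = correlations)
    } else {
      out <- list(sample_id = sample_id, status = "single",
                  primary_subtype = names(cand)[1], primary_rho = cand[[1]],
                  dual = empty_dual,
                  candidates_above_cutoff = names(cand),
                  im_status = im_status, correlations = correlations)
    }
  }
  structure(out, class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
  lab <- switch(x$status,
                unstable = "UNS",
                sprintf("%s (%.3g)", x$primary_subtype, x$primary_rho))
  if (x$status == "dual")
    lab <- paste0(lab, " / dual: ",
                  paste(sprintf("%s (%.3g)", x$dual$subtype, x$dual$rho),
                        collapse = ", "))
  cat(sprintf("<subtype_call> %s: %s, IM %s\n", x$sample_id, lab,
              x$im_status))
  invisible(x)
}

#' Score the immunomodulatory (IM) overlay
#'
#' IM is treated as a modifier on top of the subtype call, not a subtype:
#' the sample is IM-positive when its Spearman correlation with the IM
#' overlay centroid strictly exceeds \code{im_cutoff}. Without an IM
#' centroid the status is undetermined.
#'
#' @param profile named numeric vector of centered log2 values.
#' @param centroids a \code{centroid_set} (its \code{im_centroid} is used).
#' @param config a \code{\link{classifier_config}}.
#' @return \code{"positive"}, \code{"negative"} or \code{"undetermined"}.
#' @export
assess_im_status <- function(profile, centroids,
                             config = classifier_config()) {
  stopifnot(inherits(centroids, "centroid_set"))
  if (is.null(centroids$im_centroid)) return("undetermined")
  shared <- intersect(names(profile), names(centroids$im_centroid))
  if (length(shared) < 3) return("undetermined")
  x <- profile[shared]
  if (stats::sd(x) == 0) return("undetermined")
  rho <- stats::cor(x, centroids$im_centroid[shared], method = "spearman")
  if (is.na(rho)) "undetermined"
  else if (rho > config$im_cutoff) "positive" else "negative"
}

#' Classify every sample of a cohort
#'
#' The composed pipeline: gene-coverage gate, preprocessing (log2 +
#' per-batch centering as needed), per-sample centroid correlation, the
#' subtype decision tree, and the IM overlay. Deterministic given inputs
#' and configs.
#'
#' @param x an \code{expr_matrix} on any scale.
#' @param centroids a \code{centroid_set}.
#' @param pre_config a \code{\link{preprocess_config}}.
#' @param cls_config a \code{\link{classifier_config}}.
#' @param max_missing coverage gate threshold passed to
#'   \code{\link{check_gene_coverage}} (default 0.10, strict).
#' @param batch optional per-sample batch labels for centering.
#' @return a \code{\link{subtype_calls}} table, one row per sample, with
#'   attributes \code{correlations} (sample-by-subtype rho matrix),
#'   \code{coverage} (the \code{coverage_report}) and \code{configs}.
#' @export
classify_cohort <- function(x, centroids,
                            pre_config = preprocess_config(),
                            cls_config = classifier_config(),
                            max_missing = 0.10, batch = NULL) {
  stopifnot(inherits(x, "expr_matrix"), inherits(centroids, "centroid_set"))
  coverage <- check_gene_coverage(x, centroids, max_missing)
  if (!coverage$ok) {
    cond <- structure(
      class = c("coverage_error", "error", "condition"),
      list(message = sprintf(
             "coverage gate failed: %.1f%% of signature genes missing (> %.0f%%); classification refused",
             100 * coverage$missing_fraction, 100 * coverage$max_missing),
           call = sys.call(-1), coverage = coverage))
    stop(cond)
  }
  centered <- preprocess(x, batch = batch, config = pre_config)
  calls <- lapply(colnames(centered), function(sid) {
    profile <- unclass(centered)[, sid]
    cv <- correlate_to_centroids(profile, centroids)
    im <- assess_im_status(profile, centroids, cls_config)
    call_subtype(cv, cls_config, sample_id = sid, im_status = im)
  })
  out <- as_subtype_calls(calls)
  attr(out, "correlations") <- do.call(
    rbind, lapply(calls, function(cl) cl$correlations$rho))
  rownames(attr(out, "correlations")) <- out$sample_id
  attr(out, "coverage") <- coverage
  attr(out, "configs") <- list(preprocess = pre_config,
                               classifier = cls_config)
  out
}

#' Collect individual subtype_call objects into a call table
#'
#' @param calls list of \code{subtype_call} objects.
#' @return a \code{\link{subtype_calls}} table.
#' @export
as_subtype_calls <- function(calls) {
  stopifnot(length(calls) > 0,
            all(vapply(calls, inherits, TRUE, "subtype_call")))
  subtype_calls(data.frame(
    sample_id = vapply(calls, `[[`, "", "sample_id"),
    status = vapply(calls, `[[`, "", "status"),
    primary_subtype = vapply(calls, `[[`, "", "primary_subtype"),
    primary_rho = vapply(calls, `[[`, 0, "primary_rho"),
    dual_subtypes = vapply(calls, function(cl)
      serialize_duals(cl$dual$subtype, cl$dual$rho), ""),
    im_status = vapply(calls, `[[`, "", "im_status")))
}
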