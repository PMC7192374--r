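#' Specify a synthetic expression cohort
#'
#' Defines a simulated bulk-expression cohort with the structure the
#' subtyping pipeline assumes: disjoint blocks of informative genes per
#' subtype, single-subtype samples scattered around their centroid with
#' Gaussian log2-scale noise, mixture ("dual") samples, pure-noise
#' ("unstable") samples, an IM overlay on its own gene block, and an
#' additive per-gene condition shift emulating an in vitro to xenograft
#' platform change.
#'
#' @param n_genes total genes (default 500).
#' @param subtype_names subtype labels (default BL1, BL2, M, LAR, MSL).
#' @param n_informative_per_subtype informative genes per subtype block
#'   (default 20).
#' @param separation effect size of informative genes in log2 units
#'   (default 2.0).
#' @param noise_sd per-gene Gaussian noise SD in log2 units (default 1.0).
#' @param n_per_subtype single-subtype samples per subtype (default 10).
#' @param dual_fraction fraction of the cohort that is dual-subtype
#'   mixtures (default 0.1).
#' @param dual_mixing weight of the first subtype in a dual mixture, in
#'   (0, 1) (default 0.5).
#' @param unstable_fraction fraction of the cohort that is pure noise
#'   (default 0.1).
#' @param im_fraction probability a sample carries the IM overlay
#'   (default 0.3).
#' @param im_effect IM overlay effect size in log2 units (default 2.0).
#' @param batch_shift_sd SD of the per-gene additive condition shift in
#'   log2 units (default 1.0).
#' @param seed integer seed; mandatory, drives every random draw.
#' @return object of class \code{synthetic_cohort_spec}.
#' @export
synthetic_cohort_spec <- function(n_genes = 500,
                                  subtype_names = c("BL1", "BL2", "M",
                                                    "LAR", "MSL"),
                                  n_informative_per_subtype = 20,
                                  separation = 2.0,
                                  noise_sd = 1.0,
                                  n_per_subtype = 10,
                                  dual_fraction = 0.1,
                                  dual_mixing = 0.5,
                                  unstable_fraction = 0.1,
                                  im_fraction = 0.3,
                                  im_effect = 2.0,
                                  batch_shift_sd = 1.0,
                                  seed) {
  if (missing(seed))
    stop("`seed` is mandatory for a synthetic cohort spec", call. = FALSE)
  subtype_names <- as.character(subtype_names)
  k <- length(subtype_names)
  if (k < 2 || anyDuplicated(subtype_names))
    stop("need >= 2 unique subtype names", call. = FALSE)
  if (n_genes < (k + 1) * n_informative_per_subtype)
    stop("n_genes too small for ", k, " disjoint informative blocks plus ",
         "an IM block", call. = FALSE)
  for (f in c(dual_fraction, unstable_fraction, im_fraction))
    if (f < 0 || f > 1) stop("fractions must be in [0, 1]", call. = FALSE)
  if (dual_fraction + unstable_fraction >= 1)
    stop("dual_fraction + unstable_fraction must leave room for singles",
         call. = FALSE)
  if (dual_mixing <= 0 || dual_mixing >= 1)
    stop("`dual_mixing` must be in (0, 1)", call. = FALSE)
  if (n_per_subtype < 1 || n_informative_per_subtype < 1)
    stop("counts must be positive", call. = FALSE)
  if (noise_sd < 0 || batch_shift_sd < 0 || separation < 0)
    stop("separation, noise_sd and batch_shift_sd must be >= 0",
         call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 subtype_names = subtype_names,
                 n_informative_per_subtype =
                   as.integer(n_informative_per_subtype),
                 separation = separation, noise_sd = noise_sd,
                 n_per_subtype = as.integer(n_per_subtype),
                 dual_fraction = dual_fraction, dual_mixing = dual_mixing,
                 unstable_fraction = unstable_fraction,
                 im_fraction = im_fraction, im_effect = im_effect,
                 batch_shift_sd = batch_shift_sd,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

## Baseline log2 expression added before exponentiation so emitted linear
## values sit in a plausible FPKM range (2^5 = 32).
.base_log2 <- 5

## Per-purpose derived seeds keep the generator streams independent: adding
## samples never reshuffles earlier draws. Kept below 2^31 - 1.
derive_seed <- function(seed, stream, index = 0L) {
  (as.double(seed) * 48271 + stream * 7919 + index) %% 2147483629
}

#' Generate subtype centroids for a synthetic cohort
#'
#' Each subtype receives +separation on its own disjoint block of
#' informative genes and 0 elsewhere; the IM overlay centroid places
#' +im_effect on a further disjoint block. Deterministic given the spec.
#'
#' @param spec a \code{\link{synthetic_cohort_spec}}.
#' @return a \code{\link{centroid_set}} with an IM overlay centroid.
#' @export
generate_centroids <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  if (spec$separation == 0)
    warning("separation = 0: all subtype centroids are identical",
            call. = FALSE)
  k <- length(spec$subtype_names)
  m <- spec$n_informative_per_subtype
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  vals <- matrix(0, spec$n_genes, k,
                 dimnames = list(genes, spec$subtype_names))
  for (i in seq_len(k))
    vals[((i - 1) * m + 1):(i * m), i] <- spec$separation
  im <- numeric(spec$n_genes)
  im[(k * m + 1):((k + 1) * m)] <- spec$im_effect
  centroid_set(vals, im_centroid = im, algorithm = "synthetic")
}

## Sample plan: deterministic composition of the cohort. Singles first
## (blocked by subtype), then dual mixtures cycling over subtype pairs,
## then unstable samples.
sample_plan <- function(spec) {
  k <- length(spec$subtype_names)
  n_singles <- k * spec$n_per_subtype
  denom <- 1 - spec$dual_fraction - spec$unstable_fraction
  n_total <- round(n_singles / denom)
  n_dual <- round(n_total * spec$dual_fraction)
  n_uns <- round(n_total * spec$unstable_fraction)
  pairs <- utils::combn(spec$subtype_names, 2)
  plan <- data.frame(
    truth_type = c(rep("single", n_singles), rep("dual", n_dual),
                   rep("unstable", n_uns)),
    subtype_a = c(rep(spec$subtype_names, each = spec$n_per_subtype),
                  pairs[1, rep_len(seq_len(ncol(pairs)), n_dual)],
                  rep(NA_character_, n_uns)),
    subtype_b = c(rep(NA_character_, n_singles),
                  pairs[2, rep_len(seq_len(ncol(pairs)), n_dual)],
                  rep(NA_character_, n_uns)))
  plan$sample_id <- sprintf("s%03d", seq_len(nrow(plan)))
  plan
}

#' Generate a synthetic expression cohort
#'
#' Draws, on the centered log2 scale, single samples as centroid + noise,
#' dual samples as a dual_mixing-weighted mixture of two centroids + noise,
#' and unstable samples as pure noise; IM-positive samples (Bernoulli
#' im_fraction, drawn from each sample's own seed stream) additionally
#' receive the IM overlay. Values are then exponentiated
#' (2^(x + 5)) to an FPKM-like linear scale so the full pipeline, including
#' the log2 transform and centering, is exercised. Fully deterministic
#' given spec and seed.
#'
#' @param spec a \code{\link{synthetic_cohort_spec}}.
#' @param centroids a \code{centroid_set}, normally from
#'   \code{\link{generate_centroids}}.
#' @return list: \code{matrix} (linear-scale \code{expr_matrix}) and
#'   \code{truth} (a planting record data.frame: sample_id, truth_type,
#'   subtype_a, subtype_b, im_truth, batch; attribute
#'   \code{informative_genes} maps genes to their block).
#' @export
generate_cohort <- function(spec, centroids = generate_centroids(spec)) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"),
            inherits(centroids, "centroid_set"))
  if (!all(spec$subtype_names %in% colnames(centroids$values)))
    stop("centroid set lacks subtype(s) named in the spec", call. = FALSE)
  plan <- sample_plan(spec)
  genes <- rownames(centroids$values)
  vals <- matrix(NA_real_, length(genes), nrow(plan),
                 dimnames = list(genes, plan$sample_id))
  im_truth <- logical(nrow(plan))
  has_im <- !is.null(centroids$im_centroid)
  for (i in seq_len(nrow(plan))) {
    set.seed(derive_seed(spec$seed, 1L, i))
    base <- switch(plan$truth_type[i],
      single = centroids$values[, plan$subtype_a[i]],
      dual = spec$dual_mixing * centroids$values[, plan$subtype_a[i]] +
        (1 - spec$dual_mixing) * centroids$values[, plan$subtype_b[i]],
      unstable = numeric(length(genes)))
    im_truth[i] <- has_im && stats::runif(1) < spec$im_fraction
    if (im_truth[i]) base <- base + centroids$im_centroid
    vals[, i] <- base + stats::rnorm(length(genes), 0, spec$noise_sd)
  }
  truth <- data.frame(plan[c("sample_id", "truth_type", "subtype_a",
                             "subtype_b")],
                      im_truth = im_truth, batch = "invitro")
  k <- length(spec$subtype_names)
  m <- spec$n_informative_per_subtype
  block <- rep(NA_character_, length(genes))
  for (i in seq_len(k)) block[((i - 1) * m + 1):(i * m)] <-
    spec$subtype_names[i]
  block[(k * m + 1):((k + 1) * m)] <- "IM"
  attr(truth, "informative_genes") <-
    data.frame(gene_id = genes, block = block)
  mat <- expression_matrix(2^(vals + .base_log2), scale = "linear",
                           batch = truth$batch)
  list(matrix = mat, truth = truth)
}

#' Apply an additive per-gene condition shift
#'
#' Emulates moving the cohort to a second condition (e.g. xenograft
#' profiling on a different platform): every sample receives the same
#' per-gene shift, drawn Gaussian(0, batch_shift_sd) on the log2 scale —
#' exactly the kind of artifact per-batch gene centering removes. The batch
#' label is updated so downstream centering treats the shifted cohort as
#' its own batch. Deterministic given the spec.
#'
#' @param x an \code{expr_matrix} from \code{\link{generate_cohort}}.
#' @param spec the \code{\link{synthetic_cohort_spec}}.
#' @param condition_label batch label for the shifted cohort
#'   (default "xenograft").
#' @return an \code{expr_matrix} on the same scale as the input.
#' @export
apply_condition_shift <- function(x, spec, condition_label = "xenograft") {
  stopifnot(inherits(x, "expr_matrix"),
            inherits(spec, "synthetic_cohort_spec"))
  set.seed(derive_seed(spec$seed, 2L))
  shift <- stats::rnorm(nrow(x), 0, spec$batch_shift_sd)
  vals <- unclass(x)
  vals <- if (expr_scale(x) == "linear") vals * 2^shift else vals + shift
  expression_matrix(vals, scale = expr_scale(x),
                    batch = rep(condition_label, ncol(x)))
}
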