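five_centroids <- function(n_genes = 50, seed = 11) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * 5), n_genes, 5,
                 dimnames = list(sprintf("g%02d", 1:n_genes),
                                 c("BL1", "BL2", "M", "LAR", "MSL")))
  centroid_set(vals)
}

test_that("centroid correlation is a rank correlation over shared genes", {
  cen <- five_centroids()
  genes <- rownames(cen$values)

  # self-correlation
  cv <- correlate_to_centroids(setNames(cen$values[, "BL1"], genes), cen)
  expect_equal(cv$rho[["BL1"]], 1.0)
  expect_equal(cv$n_genes_used, 50)

  # invariant to a strictly increasing transform (cube)
  cv3 <- correlate_to_centroids(setNames(cen$values[, "M"]^3, genes), cen)
  expect_equal(cv3$rho[["M"]], 1.0)

  # reversed ranks
  small <- centroid_set(matrix(c(5, 4, 3, 2, 1, 1, 1, 2, 2, 3), 5, 2,
                               dimnames = list(paste0("g", 1:5),
                                               c("A", "B"))))
  cvr <- correlate_to_centroids(
    c(g1 = 1, g2 = 2, g3 = 3, g4 = 4, g5 = 5), small)
  expect_equal(cvr$rho[["A"]], -1.0)

  # only the gene intersection is used
  cv_sub <- correlate_to_centroids(
    setNames(cen$values[1:10, "BL2"], genes[1:10]), cen)
  expect_equal(cv_sub$n_genes_used, 10)
  expect_equal(cv_sub$rho[["BL2"]], 1.0)

  expect_error(correlate_to_centroids(c(g01 = 1, g02 = 2), cen),
               "at least 3")
  expect_warning(
    cv0 <- correlate_to_centroids(setNames(rep(0, 50), genes), cen),
    "zero variance")
  expect_true(all(is.na(cv0$rho)))
  expect_identical(call_subtype(cv0)$status, "unstable")
})

test_that("Spearman matches the brute-force rank oracle, ties included", {
  # worked 6-gene case with one tie pair
  x <- c(1.2, 3.4, 3.4, 0.5, 2.2, 9.0)
  y <- c(2.0, 1.0, 4.0, 0.3, 0.3, 5.0)
  names(x) <- names(y) <- paste0("g", 1:6)
  cen <- centroid_set(cbind(A = y, B = rev(y)))
  cv <- correlate_to_centroids(x, cen)
  expect_equal(cv$rho[["A"]], spearman_bruteforce(x, y),
               tolerance = 1e-12)

  set.seed(42)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    a <- sample(c(rnorm(n - 2), rep(round(rnorm(1), 1), 2)))
    b <- sample(c(rnorm(n - 1), a[1]))
    names(a) <- names(b) <- paste0("g", seq_len(n))
    cen_i <- centroid_set(cbind(A = b, B = -b))
    expect_equal(correlate_to_centroids(a, cen_i)$rho[["A"]],
                 spearman_bruteforce(a, b), tolerance = 1e-12)
  }
})

test_that("the correlation-difference z test follows the Fisher formula", {
  eq <- test_correlation_difference(0.3, 0.3, 101)
  expect_equal(eq$z_statistic, 0)
  expect_false(eq$significant)

  # direct evaluation of the formula at the HCC70-style rho pair
  res <- test_correlation_difference(0.27, 0.17, 101)
  expect_equal(res$z_statistic,
               (atanh(0.27) - atanh(0.17)) / sqrt(2 * 1.06 / 98),
               tolerance = 1e-12)
  expect_equal(res$z_statistic, 0.71, tolerance = 0.01)
  expect_false(res$significant)

  far <- test_correlation_difference(0.9, 0.0, 101)
  expect_true(far$significant)
  expect_equal(far$z_statistic, 10, tolerance = 0.01)

  expect_warning(clip <- test_correlation_difference(1, 0, 101),
                 "clipped")
  expect_true(is.finite(clip$z_statistic))
  expect_error(test_correlation_difference(0.5, 0.1, 3), ">= 4")

  # dependent (Steiger) variant is offered and direction-consistent
  st <- test_correlation_difference(
    0.27, 0.17, 101, classifier_config(tie_test = "steiger"), rho_ab = 0.3)
  expect_false(st$significant)
  expect_gt(st$z_statistic, 0)
})

test_that("the decision tree assigns single, dual and unstable correctly", {
  cfg <- classifier_config()

  uns <- call_subtype(make_cv(
    c(BL1 = 0.05, BL2 = 0.02, M = -0.10, LAR = 0.00, MSL = 0.04)), cfg)
  expect_identical(uns$status, "unstable")
  expect_true(is.na(uns$primary_subtype))
  expect_length(uns$candidates_above_cutoff, 0)

  lar <- call_subtype(make_cv(
    c(BL1 = 0.01, BL2 = 0.05, M = -0.2, LAR = 0.53, MSL = 0.1)), cfg,
    sample_id = "MDAMB453")
  expect_identical(lar$status, "single")
  expect_identical(lar$primary_subtype, "LAR")
  expect_equal(lar$primary_rho, 0.53)

  # two candidates, non-significant difference -> dual ranked by rho
  dual <- call_subtype(make_cv(
    c(BL1 = 0.0, BL2 = 0.27, M = 0.17, LAR = 0.05, MSL = -0.1),
    n_genes = 101), cfg, sample_id = "HCC70")
  expect_identical(dual$status, "dual")
  expect_identical(dual$primary_subtype, "BL2")
  expect_equal(dual$dual, data.frame(subtype = "M", rho = 0.17))

  # two candidates, significant difference -> predominant single
  pred <- call_subtype(make_cv(
    c(BL1 = 0.9, BL2 = 0.12, M = 0, LAR = 0, MSL = 0), n_genes = 101),
    cfg)
  expect_identical(pred$status, "single")
  expect_identical(pred$primary_subtype, "BL1")

  # rho exactly at the cutoff is NOT a candidate (strict inequality)
  expect_identical(call_subtype(make_cv(
    c(BL1 = 0.1, BL2 = 0.1, M = 0.1, LAR = 0.1, MSL = 0.1)),
    cfg)$status, "unstable")

  # exact tie at the top: dual, alphabetical order
  tie <- call_subtype(make_cv(
    c(M = 0.3, BL2 = 0.3, BL1 = 0.0, LAR = 0.0, MSL = 0.0),
    n_genes = 101), cfg)
  expect_identical(tie$status, "dual")
  expect_identical(tie$primary_subtype, "BL2")
  expect_identical(tie$dual$subtype, "M")

  # >2 candidates: significantly-lower ones drop off the dual list
  mixed <- call_subtype(make_cv(
    c(BL1 = 0.85, BL2 = 0.80, M = 0.15, LAR = 0, MSL = 0),
    n_genes = 101), cfg)
  expect_identical(mixed$status, "dual")
  expect_identical(mixed$dual$subtype, "BL2")
})

test_that("every correlation vector yields exactly one status", {
  set.seed(19)
  cfg <- classifier_config()
  for (i in 1:200) {
    rho <- setNames(runif(5, -1, 1) * 0.99,
                    c("BL1", "BL2", "M", "LAR", "MSL"))
    call <- call_subtype(make_cv(rho, n_genes = sample(10:500, 1)), cfg)
    expect_true(call$status %in% c("single", "dual", "unstable"))
    above <- sum(rho > cfg$cutoff)
    if (above == 0) expect_identical(call$status, "unstable")
    if (above == 1) expect_identical(call$status, "single")
    if (above >= 1)
      expect_identical(call$primary_subtype,
                       names(which.max(rho)))
    if (call$status != "unstable") expect_gt(call$primary_rho, cfg$cutoff)
    # raising the cutoff never rescues an unstable call
    stricter <- call_subtype(make_cv(rho), classifier_config(cutoff = 0.3))
    if (call$status == "unstable")
      expect_identical(stricter$status, "unstable")
  }
})

test_that("IM status is an overlay with its own cutoff", {
  set.seed(5)
  genes <- paste0("g", 1:30)
  im <- rnorm(30)
  cen <- centroid_set(
    matrix(rnorm(60), 30, 2, dimnames = list(genes, c("A", "B"))),
    im_centroid = im)
  expect_identical(assess_im_status(setNames(im, genes), cen), "positive")
  expect_identical(assess_im_status(setNames(-im, genes), cen), "negative")
  no_im <- centroid_set(cen$values)
  expect_identical(assess_im_status(setNames(im, genes), no_im),
                   "undetermined")
})

test_that("cohort classification composes the gate, transform and calls", {
  cen <- five_centroids(n_genes = 40)
  # exact centroid copies on the centered scale: every rho is 1
  m <- centered_matrix(cen$values, genes = rownames(cen$values),
                       samples = paste0("copy_", subtype_names(cen)))
  calls <- classify_cohort(m, cen)
  expect_identical(calls$primary_subtype, subtype_names(cen))
  expect_equal(calls$primary_rho, rep(1, 5))
  expect_identical(unique(calls$status), "single")

  # permuting samples permutes the calls
  perm <- c(3, 1, 5, 2, 4)
  m_perm <- centered_matrix(cen$values[, perm],
                            genes = rownames(cen$values),
                            samples = colnames(m)[perm])
  calls_perm <- classify_cohort(m_perm, cen)
  expect_equal(as.data.frame(calls_perm),
               as.data.frame(calls[perm, ]), ignore_attr = TRUE)

  # gene-order invariance (consistent permutation of rows)
  gperm <- sample(nrow(cen$values))
  calls_g <- classify_cohort(
    centered_matrix(unclass(m)[gperm, ],
                    genes = rownames(cen$values)[gperm],
                    samples = colnames(m)),
    cen)
  expect_equal(calls_g$primary_rho, calls$primary_rho)
  expect_identical(calls_g$primary_subtype, calls$primary_subtype)

  # coverage refusal carries the report
  tiny <- centered_matrix(unclass(m)[1:20, , drop = FALSE],
                          genes = rownames(cen$values)[1:20],
                          samples = colnames(m))
  err <- tryCatch(classify_cohort(tiny, cen), coverage_error = identity)
  expect_s3_class(err, "coverage_error")
  expect_equal(err$coverage$missing_fraction, 0.5)

  # attributes document the run
  expect_true(inherits(attr(calls, "coverage"), "coverage_report"))
  expect_equal(dim(attr(calls, "correlations")), c(5, 5))
})

test_that("rank invariance: monotone rescaling never changes a call", {
  cen <- five_centroids(n_genes = 30, seed = 2)
  set.seed(8)
  profile <- setNames(cen$values[, "LAR"] + rnorm(30, 0, 0.5),
                      rownames(cen$values))
  base <- call_subtype(correlate_to_centroids(profile, cen))
  for (f in list(function(x) x^3, function(x) exp(x),
                 function(x) 5 * x + 2)) {
    tr <- call_subtype(correlate_to_centroids(f(profile), cen))
    expect_identical(tr$status, base$status)
    expect_identical(tr$primary_subtype, base$primary_subtype)
    expect_equal(tr$correlations$rho, base$correlations$rho)
  }
})

test_that("pure-noise cohorts classify overwhelmingly as unstable", {
  set.seed(31)
  n_genes <- 400
  genes <- sprintf("g%03d", 1:n_genes)
  cen <- centroid_set(matrix(rnorm(n_genes * 5), n_genes, 5,
                             dimnames = list(genes, c("BL1", "BL2", "M",
                                                      "LAR", "MSL"))))
  noise <- matrix(rnorm(n_genes * 40), n_genes, 40,
                  dimnames = list(genes, sprintf("s%02d", 1:40)))
  calls <- classify_cohort(expression_matrix(noise,
                                             scale = "log2_centered"), cen)
  # sd of a null Spearman rho at n = 400 is ~0.05, so rho > 0.1 is rare
  expect_gt(mean(calls$status == "unstable"), 0.8)
})
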