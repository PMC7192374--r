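# Independent brute-force Spearman oracle: explicit average-rank
# computation plus the Pearson product-moment formula, no calls to cor()
# or rank().
average_ranks <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
}

spearman_bruteforce <- function(x, y) {
  rx <- average_ranks(x)
  ry <- average_ranks(y)
  dx <- rx - sum(rx) / length(rx)
  dy <- ry - sum(ry) / length(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Small centered-log2 matrix builder for classifier tests.
centered_matrix <- function(values, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, scale = "log2_centered")
}

# Build a correlation_vector directly (bypassing the data path) so the
# decision tree can be property-tested over arbitrary rho vectors.
make_cv <- function(rho, n_genes = 101) {
  structure(list(rho = rho, n_genes_used = n_genes,
                 zero_variance = FALSE),
            class = "correlation_vector")
}

# Minimal valid call table.
make_calls <- function(sample_id, primary, rho = 0.5,
                       status = NULL, dual = "", im = "undetermined") {
  if (is.null(status))
    status <- ifelse(is.na(primary), "unstable",
                     ifelse(nzchar(dual), "dual", "single"))
  subtype_calls(data.frame(
    sample_id = sample_id, status = status, primary_subtype = primary,
    primary_rho = ifelse(is.na(primary), NA_real_, rho),
    dual_subtypes = dual, im_status = im))
}
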