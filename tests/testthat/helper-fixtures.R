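# Small in-code fixtures shared across test files.

# A named expression matrix from raw numbers.
make_expr <- function(values, detection_p = NULL, scale = "raw") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  if (!is.null(detection_p)) dimnames(detection_p) <- dimnames(values)
  expression_matrix(values, detection_p = detection_p, scale = scale)
}

# A linear_fit object with prescribed residual variances, for testing
# the moderation step in isolation.
make_fit <- function(sigma2, df, beta = rep(1, length(sigma2)), v = 1) {
  structure(list(coefficients = cbind(tested = beta), sigma2 = sigma2,
                 df_residual = df, cov_unscaled_diag = c(tested = v),
                 design = NULL),
            class = "linear_fit")
}

.read_tsv_for_tests <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

# Default small cohort used by several module tests.
small_cohort <- function(seed = 42, n = 600, probes = 400,
                         beta = c(0.45, 0.45), n_affected = 10,
                         prevalence = 0.15, n_batches = 1, ...) {
  generate_cohort(sim_config(
    n_samples = n, n_probes = probes, n_genes = round(probes * 0.8),
    n_batches = n_batches,
    substances = list(substance_spec("drugA", prevalence, n_affected, beta)),
    seed = seed, ...))
}
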