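#' Filter probes by detection p-value
#'
#' A probe is kept when it is detected (detection p-value <= `alpha`) in
#' at least a fraction `min_fraction` of samples (boundary inclusive).
#' Probes failing this are considered not sufficiently expressed.
#'
#' @param expr an [expression_matrix()] carrying detection p-values.
#' @param alpha detection p-value cut-off per entry (default 0.05).
#' @param min_fraction minimum fraction of samples in which the probe
#'   must be detected (default 0.05).
#' @return A probe mask data.frame with columns `id`, `keep`, `reason`
#'   and `score` (the detected-sample fraction).
#' @export
detection_filter <- function(expr, alpha = 0.05, min_fraction = 0.05) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (is.null(expr$detection_p))
    stop("detection_filter: no detection p-values present; ",
         "skip this stage explicitly if your platform provides none")
  frac <- rowMeans(expr$detection_p <= alpha)
  keep <- frac >= min_fraction
  data.frame(id = rownames(expr$values), keep = keep,
             reason = ifelse(keep, "", "not_expressed"),
             score = frac, row.names = NULL, stringsAsFactors = FALSE)
}

#' Quantile-normalize a raw expression matrix
#'
#' Forces every sample (column) to share the same distribution: after
#' normalization each sample's sorted values equal the mean of the
#' samples' order statistics. Delegates to [limma::normalizeQuantiles()].
#'
#' @param expr an [expression_matrix()] on the raw scale.
#' @return A new `expr_matrix`, still tagged raw, with detection p-values
#'   carried through unchanged.
#' @export
quantile_normalize <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  v <- .expr_values(expr, require_scale = "raw")
  if (ncol(v) < 2)
    stop("quantile_normalize: need at least 2 samples")
  out <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(out) <- dimnames(v)
  expression_matrix(out, detection_p = expr$detection_p, scale = "raw")
}

#' Log2-transform an expression matrix
#'
#' @param expr an [expression_matrix()] on the raw scale.
#' @param offset value added before taking log2 (default 0; use a small
#'   pseudo-offset for matrices containing values <= 0 after background
#'   handling upstream).
#' @return The matrix on the log2 scale (scale tag updated).
#' @export
log2_transform <- function(expr, offset = 0) {
  stopifnot(inherits(expr, "expr_matrix"))
  v <- .expr_values(expr, require_scale = "raw") + offset
  bad <- which(v <= 0)
  if (length(bad)) {
    rc <- arrayInd(utils::head(bad, 5), dim(v))
    stop("log2_transform: non-positive values after offset at (probe, sample): ",
         paste(sprintf("(%s, %s)", rownames(v)[rc[, 1]], colnames(v)[rc[, 2]]),
               collapse = ", "),
         if (length(bad) > 5) sprintf(" and %d more", length(bad) - 5) else "")
  }
  expression_matrix(log2(v), detection_p = expr$detection_p, scale = "log2")
}

#' Mahalanobis-distance sample quality control
#'
#' Computes, for each sample, the Mahalanobis distance between its QC
#' feature vector and an artificial sample holding the feature means,
#' using the sample covariance of the features. Samples farther than
#' `median + k_iqr * IQR` of the distance distribution are flagged for
#' removal (one-sided upper fence; distances are non-negative and only
#' large values indicate failure).
#'
#' @param qc samples x features numeric matrix (missing values are
#'   mean-imputed with a warning).
#' @param k_iqr fence multiplier (default 4).
#' @param ridge if `TRUE`, add a small ridge to a singular covariance
#'   instead of failing (off by default).
#' @return A sample mask data.frame (`id`, `keep`, `reason`, `score` =
#'   the Mahalanobis distance).
#' @export
mahalanobis_qc <- function(qc, k_iqr = 4, ridge = FALSE) {
  if (!is.matrix(qc) || !is.numeric(qc))
    stop("mahalanobis_qc: 'qc' must be a numeric matrix (samples x features)")
  if (ncol(qc) < 1) stop("mahalanobis_qc: need >= 1 QC feature")
  if (nrow(qc) <= ncol(qc) + 1)
    stop("mahalanobis_qc: need more samples than features + 1")
  if (anyNA(qc)) {
    warning("mahalanobis_qc: missing QC features mean-imputed")
    for (j in seq_len(ncol(qc))) {
      miss <- is.na(qc[, j])
      qc[miss, j] <- mean(qc[, j], na.rm = TRUE)
    }
  }
  ctr <- colMeans(qc)
  S <- stats::cov(qc)
  if (rcond(S) < 1e-12) {
    if (!ridge)
      stop("mahalanobis_qc: singular QC feature covariance; ",
           "prune redundant features or set ridge = TRUE")
    S <- S + diag(1e-8 * mean(diag(S)), ncol(S))
  }
  d <- sqrt(stats::mahalanobis(qc, ctr, S))
  fence <- stats::median(d) + k_iqr * stats::IQR(d)
  keep <- d <= fence
  data.frame(id = rownames(qc), keep = keep,
             reason = ifelse(keep, "", "mahalanobis_outlier"),
             score = d, row.names = NULL, stringsAsFactors = FALSE)
}

#' Empirical-Bayes batch adjustment (location and scale)
#'
#' Parametric empirical-Bayes adjustment of known batch effects, the
#' location/scale model used for expression chips: per probe, the data
#' are standardized by the overall model fit, per-batch location and
#' scale estimates are shrunk toward normal / inverse-gamma priors whose
#' hyperparameters are estimated across probes by method of moments, and
#' the shrunken estimates (found by fixed-point iteration of the
#' conditional posterior means) are removed.
#'
#' With a single batch the input is returned unchanged. Every batch must
#' contain at least two samples; drop offending samples first.
#'
#' @param expr an [expression_matrix()] on the log2 scale.
#' @param batch factor (or coercible) of batch ids, one per sample.
#' @param covariates optional samples x k numeric design of biological
#'   covariates to protect during standardization (no intercept).
#' @param tol convergence tolerance of the fixed-point iteration
#'   (default 1e-4).
#' @param max_iter iteration cap (default 100).
#' @return A list with `expr` (adjusted matrix, log2 scale) and `model`
#'   (a `batch_model`: per-batch per-probe `gamma_star`, `delta_star` and
#'   the prior hyperparameters).
#' @export
combat_adjust <- function(expr, batch, covariates = NULL,
                          tol = 1e-4, max_iter = 100) {
  stopifnot(inherits(expr, "expr_matrix"))
  y <- .expr_values(expr, require_scale = "log2")
  batch <- factor(batch)
  if (length(batch) != ncol(y))
    stop("combat_adjust: 'batch' must have one entry per sample")
  nb <- table(batch)
  if (nlevels(batch) == 1) {
    model <- structure(list(batches = levels(batch), gamma_star = NULL,
                            delta_star = NULL, hyper = NULL,
                            note = "single batch: no adjustment"),
                       class = "batch_model")
    return(list(expr = expr, model = model))
  }
  if (any(nb < 2))
    stop("combat_adjust: batch(es) with a single sample: ",
         paste(names(nb)[nb < 2], collapse = ", "),
         "; drop those samples before adjustment")

  n <- ncol(y); G <- nrow(y); B <- nlevels(batch)
  bm <- stats::model.matrix(~ 0 + batch)          # n x B indicators
  X <- if (is.null(covariates)) bm else {
    cv <- as.matrix(covariates)
    if (nrow(cv) != n) stop("combat_adjust: 'covariates' rows must match samples")
    cbind(bm, cv)
  }
  if (qr(X)$rank < ncol(X))
    stop("combat_adjust: covariates confounded with batch (rank-deficient design)")

  # per-probe OLS fit of batch means (+ covariates)
  beta_hat <- solve(crossprod(X), crossprod(X, t(y)))      # ncol(X) x G
  w <- as.numeric(nb) / n
  grand <- crossprod(beta_hat[seq_len(B), , drop = FALSE], w)  # G x 1
  stand_mean <- matrix(grand, G, n)
  if (!is.null(covariates))
    stand_mean <- stand_mean +
      t(X[, -(seq_len(B)), drop = FALSE] %*%
          beta_hat[-(seq_len(B)), , drop = FALSE])
  var_pooled <- rowMeans((y - t(X %*% beta_hat))^2)
  if (any(var_pooled <= 0))
    stop("combat_adjust: probe(s) with zero pooled variance")
  s_data <- (y - stand_mean) / sqrt(var_pooled)

  gamma_hat <- delta_hat <- matrix(NA_real_, B, G,
                                   dimnames = list(levels(batch), rownames(y)))
  for (b in seq_len(B)) {
    in_b <- batch == levels(batch)[b]
    gamma_hat[b, ] <- rowMeans(s_data[, in_b, drop = FALSE])
    delta_hat[b, ] <- apply(s_data[, in_b, drop = FALSE], 1, stats::var)
  }
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, stats::var)
  m_d <- rowMeans(delta_hat)
  v_d <- apply(delta_hat, 1, stats::var)
  a_prior <- (2 * v_d + m_d^2) / v_d
  b_prior <- (m_d * v_d + m_d^3) / v_d

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_len(B)) {
    in_b <- batch == levels(batch)[b]
    sd_b <- s_data[, in_b, drop = FALSE]
    n_b <- sum(in_b)
    g_old <- gamma_hat[b, ]; d_old <- delta_hat[b, ]
    for (it in seq_len(max_iter)) {
      g_new <- (t2[b] * n_b * gamma_hat[b, ] + d_old * gamma_bar[b]) /
        (t2[b] * n_b + d_old)
      sum2 <- rowSums((sd_b - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[b]) / (n_b / 2 + a_prior[b] - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
      if (change < tol) break
    }
    gamma_star[b, ] <- g_old
    delta_star[b, ] <- d_old
  }

  adj <- s_data
  for (b in seq_len(B)) {
    in_b <- batch == levels(batch)[b]
    adj[, in_b] <- (s_data[, in_b, drop = FALSE] - gamma_star[b, ]) /
      sqrt(delta_star[b, ])
  }
  adj <- adj * sqrt(var_pooled) + stand_mean

  model <- structure(list(batches = levels(batch),
                          gamma_star = gamma_star, delta_star = delta_star,
                          hyper = list(gamma_bar = gamma_bar, t2 = t2,
                                       a_prior = a_prior, b_prior = b_prior)),
                     class = "batch_model")
  list(expr = expression_matrix(adj, detection_p = expr$detection_p,
                                scale = "log2"),
       model = model)
}

#' @export
print.batch_model <- function(x, ...) {
  cat(sprintf("Empirical-Bayes batch model: %d batch(es)%s\n",
              length(x$batches),
              if (is.null(x$gamma_star)) " (no adjustment)" else ""))
  invisible(x)
}

#' Check batch-effect removal by one-way ANOVA
#'
#' Per probe, an F-test of expression on the batch factor. After a
#' successful adjustment the fraction of probes with p < 0.05 should be
#' close to the nominal 0.05.
#'
#' @param expr an [expression_matrix()] or numeric matrix (probes x
#'   samples).
#' @param batch factor of batch ids, >= 2 levels, each with >= 2 samples.
#' @return A list with `p` (per-probe F-test p-values) and
#'   `frac_significant` (fraction with p < 0.05).
#' @export
batch_anova_check <- function(expr, batch) {
  y <- .expr_values(expr)
  batch <- factor(batch)
  if (nlevels(batch) < 2) stop("batch_anova_check: need >= 2 batches")
  n <- ncol(y); k <- nlevels(batch)
  ind <- stats::model.matrix(~ 0 + batch)
  nb <- colSums(ind)
  gm <- (y %*% ind) / matrix(nb, nrow(y), k, byrow = TRUE)  # group means
  overall <- rowMeans(y)
  ssb <- rowSums(sweep(gm, 2, nb, `*`) * gm) - n * overall^2
  sst <- rowSums(y^2) - n * overall^2
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  names(p) <- rownames(y)
  list(p = p, frac_significant = mean(p < 0.05))
}

#' Euclidean-distance expression outlier filter
#'
#' Builds an artificial average sample from the data after setting aside
#' the `trim` fraction of samples farthest from the overall mean, then
#' flags samples whose Euclidean distance to this trimmed mean exceeds
#' `median + k_iqr * IQR` (median and IQR over all samples).
#'
#' @param expr an [expression_matrix()] or numeric matrix (probes x
#'   samples), at least 10 samples.
#' @param trim fraction of farthest samples excluded from the reference
#'   mean (default 0.10).
#' @param k_iqr fence multiplier (default 4).
#' @return A sample mask data.frame (`id`, `keep`, `reason`, `score` =
#'   distance to the trimmed mean).
#' @export
euclidean_outlier_filter <- function(expr, trim = 0.10, k_iqr = 4) {
  y <- .expr_values(expr)
  n <- ncol(y)
  if (n < 10) stop("euclidean_outlier_filter: need >= 10 samples")
  if (trim < 0 || trim >= 0.5)
    stop("euclidean_outlier_filter: 'trim' must lie in [0, 0.5)")
  m0 <- rowMeans(y)
  d0 <- sqrt(colSums((y - m0)^2))
  n_trim <- floor(trim * n)
  keep_ref <- if (n_trim > 0) order(d0, decreasing = TRUE)[-seq_len(n_trim)]
  else seq_len(n)
  m1 <- rowMeans(y[, sort(keep_ref), drop = FALSE])
  d <- sqrt(colSums((y - m1)^2))
  fence <- stats::median(d) + k_iqr * stats::IQR(d)
  keep <- d <= fence
  data.frame(id = colnames(y), keep = keep,
             reason = ifelse(keep, "", "euclidean_outlier"),
             score = d, row.names = NULL, stringsAsFactors = FALSE)
}
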