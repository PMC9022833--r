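#' Per-probe ordinary least squares fits
#'
#' Fits the same linear design to every probe at once. Returns the pieces
#' the empirical-Bayes moderation step needs: coefficients, residual
#' variances, residual degrees of freedom and the unscaled coefficient
#' variances (the diagonal of `(X'X)^-1`).
#'
#' @param expr [expression_matrix()] (log2 scale expected) or numeric
#'   probes x samples matrix.
#' @param design samples x p numeric matrix, full rank, with column
#'   names.
#' @return A `linear_fit`: list with `coefficients` (probes x p),
#'   `sigma2`, `df_residual` (scalar), `cov_unscaled_diag` (length p) and
#'   `design`.
#' @export
fit_linear_models <- function(expr, design) {
  y <- .expr_values(expr)
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  n <- ncol(y); p <- ncol(design)
  if (nrow(design) != n)
    stop("fit_linear_models: design rows must match samples")
  qx <- qr(design)
  if (qx$rank < p) {
    dep <- colnames(design)[qx$pivot[(qx$rank + 1):p]]
    stop("fit_linear_models: rank-deficient design; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  if (n <= p) stop("fit_linear_models: need n_samples > n_columns")
  fit <- stats::lm.fit(design, t(y))
  coefs <- t(fit$coefficients)             # probes x p
  df <- n - p
  sigma2 <- colSums(fit$residuals^2) / df
  xtx_inv <- chol2inv(chol(crossprod(design)))
  v <- diag(xtx_inv)
  names(v) <- colnames(design)
  structure(list(coefficients = coefs, sigma2 = sigma2, df_residual = df,
                 cov_unscaled_diag = v, design = design),
            class = "linear_fit")
}

#' @export
coef.linear_fit <- function(object, ...) object$coefficients

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Per-probe OLS fit: %d probes, %d coefficients, %d residual df\n",
              nrow(x$coefficients), ncol(x$coefficients), x$df_residual))
  invisible(x)
}

# Inverse of the trigamma function by Newton iteration (monotone,
# convex target; converges in a handful of steps).
.trigamma_inverse <- function(y, tol = 1e-8, max_iter = 50) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < tol) break
  }
  x
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-probe residual variances toward a common prior and forms
#' moderated t-statistics for one coefficient. The prior degrees of
#' freedom `d0` and prior variance `s0^2` are estimated by moment
#' matching on `log s^2`: with
#' `e_g = log s2_g - digamma(d/2) + log(d/2)`, the excess of `var(e)`
#' over `trigamma(d/2)` determines `d0` through the trigamma inverse, and
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the excess is
#' non-positive, `d0 = Inf` and all posterior variances equal `s0^2`.
#' Otherwise `s2_post = (d0 s0^2 + d s2) / (d0 + d)`; the moderated t has
#' `d0 + d` degrees of freedom.
#'
#' @param fit a [fit_linear_models()] result (>= 10 probes).
#' @param coef coefficient to test: name or index (default: the last
#'   design column).
#' @param moderation set `FALSE` to disable shrinkage (`d0 = 0`): the
#'   ordinary t-test with `d` degrees of freedom.
#' @return A `moderated_fit`: list with `d0`, `s02`, `s2_post`, `beta`,
#'   `se`, `t`, `p`, `df_total`, `coef`.
#' @export
moderate_variances <- function(fit, coef = ncol(fit$coefficients),
                               moderation = TRUE) {
  stopifnot(inherits(fit, "linear_fit"))
  s2 <- fit$sigma2
  d <- fit$df_residual
  if (length(s2) < 10)
    stop("moderate_variances: need >= 10 probes to estimate the prior")
  if (is.character(coef)) {
    if (!coef %in% colnames(fit$coefficients))
      stop("moderate_variances: unknown coefficient '", coef, "'")
    coef <- match(coef, colnames(fit$coefficients))
  }
  beta <- fit$coefficients[, coef]
  v <- fit$cov_unscaled_diag[coef]

  if (!moderation) {
    d0 <- 0; s02 <- NA_real_; s2_post <- s2; df_total <- rep(d, length(s2))
  } else {
    pos <- s2 > 0
    if (!any(pos)) stop("moderate_variances: all residual variances are zero")
    e <- log(s2[pos]) - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    evar <- stats::var(e) - trigamma(d / 2)
    if (is.na(evar) || evar <= 0) {
      d0 <- Inf
      s02 <- exp(emean)
      s2_post <- rep(s02, length(s2))
      df_total <- rep(Inf, length(s2))
    } else {
      d0 <- 2 * .trigamma_inverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
      s2_post <- (d0 * s02 + d * s2) / (d0 + d)
      df_total <- rep(d0 + d, length(s2))
    }
  }
  se <- sqrt(s2_post * v)
  t <- beta / se
  p <- 2 * stats::pt(abs(t), df = df_total, lower.tail = FALSE)
  structure(list(d0 = d0, s02 = s02, s2_post = s2_post, beta = beta,
                 se = se, t = t, p = p, df_total = df_total,
                 coef = colnames(fit$coefficients)[coef]),
            class = "moderated_fit")
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("Moderated t (coefficient '%s'): %d probes, d0 = %s, s0^2 = %s\n",
              x$coef, length(x$t),
              format(x$d0, digits = 4), format(x$s02, digits = 4)))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up q-values controlling the false discovery rate; a thin,
#' validating wrapper around [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`, finite.
#' @return q-values in the input order, `q >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p)))
    stop("bh_adjust: p-values must be finite numbers")
  if (any(p < 0 | p > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression for one active substance
#'
#' Builds the association design (intercept + base covariates +
#' OR-screened adjustment substances + the tested substance), fits
#' per-probe linear models, moderates the variances of the tested
#' coefficient, and BH-adjusts its p-values within the substance.
#' Substances with fewer than `min_users` users are skipped (returns
#' `NULL` with a message).
#'
#' @param expr preprocessed [expression_matrix()] (log2 scale) or matrix.
#' @param annot sample annotation (see [base_design()]).
#' @param med samples x substances 0/1 matrix.
#' @param substance label of the substance to test.
#' @param model an `adjustment_model` from
#'   [select_adjustment_substances()], or `NULL` for base covariates
#'   only.
#' @param min_users minimum user count (default 20).
#' @param or_lo,or_hi odds-ratio screen bounds (defaults 0.125 / 8).
#' @param probes optional probe ids restricting the test (used in
#'   replication).
#' @param probe_annot optional probe annotation data.frame (`probe`,
#'   `gene`) used to attach gene symbols.
#' @return A `de_result`: data.frame with columns `probe`, `gene`,
#'   `beta`, `se`, `t`, `p`, `q`, `direction`, plus attributes
#'   `substance`, `n_users`, `adjustment_kept`, `adjustment_dropped`,
#'   `or_report`, `d0`, `s02`; or `NULL` when skipped.
#' @export
test_substance <- function(expr, annot, med, substance, model = NULL,
                           min_users = 20, or_lo = 0.125, or_hi = 8,
                           probes = NULL, probe_annot = NULL) {
  y <- .expr_values(expr)
  if (!substance %in% colnames(med))
    stop("test_substance: substance '", substance,
         "' absent from the medication table")
  drug <- as.numeric(med[, substance])
  if (sum(drug) < min_users) {
    message("test_substance: '", substance, "' skipped (",
            sum(drug), " users < ", min_users, ")")
    return(NULL)
  }
  if (!is.null(probes)) y <- y[probes, , drop = FALSE]

  adjustment <- if (is.null(model)) character(0) else model$substances
  screen <- pairwise_or_screen(med, substance, adjustment,
                               lo = or_lo, hi = or_hi)
  X <- base_design(annot)
  if (length(screen$kept))
    X <- cbind(X, med[, screen$kept, drop = FALSE])
  X <- cbind(X, tested = drug)
  fit <- fit_linear_models(y, X)
  mod <- moderate_variances(fit, coef = "tested")
  q <- bh_adjust(mod$p)
  gene <- rep(NA_character_, nrow(y))
  if (!is.null(probe_annot)) {
    m <- match(rownames(y), probe_annot$probe)
    gene <- probe_annot$gene[m]
  }
  res <- data.frame(probe = rownames(y), gene = gene, beta = mod$beta,
                    se = mod$se, t = mod$t, p = mod$p, q = q,
                    direction = sign(mod$beta), row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(res, class = c("de_result", "data.frame"),
            substance = substance, n_users = sum(drug),
            adjustment_kept = screen$kept,
            adjustment_dropped = screen$dropped,
            or_report = screen$report, d0 = mod$d0, s02 = mod$s02)
}

#' @export
print.de_result <- function(x, ...) {
  nsig <- sum(x$q <= 0.05)
  cat(sprintf("Differential expression for '%s' (%d users): %d probes, %d at q <= 0.05 (%d up, %d down)\n",
              attr(x, "substance"), attr(x, "n_users"), nrow(x), nsig,
              sum(x$q <= 0.05 & x$direction > 0),
              sum(x$q <= 0.05 & x$direction < 0)))
  if (length(attr(x, "adjustment_dropped")))
    cat("  adjustment drugs dropped by OR screen:",
        paste(attr(x, "adjustment_dropped"), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.de_result <- function(object, q_cut = 0.05, ...) {
  sig <- object$q <= q_cut
  data.frame(substance = attr(object, "substance"),
             n_users = attr(object, "n_users"),
             n_probes = nrow(object), n_significant = sum(sig),
             n_up = sum(sig & object$direction > 0),
             n_down = sum(sig & object$direction < 0),
             min_q = min(object$q), stringsAsFactors = FALSE)
}

#' Summarize probe-level results at the gene level
#'
#' A gene is significantly differentially expressed when at least one
#' probe mapped to it reaches `q <= q_cut`. The best probe per gene is
#' the one with minimal q (ties: larger |t|, then lexicographic probe
#' id); a probe mapped to several genes contributes to each of them.
#'
#' @param de a `de_result` from [test_substance()].
#' @param probe_annot data.frame with columns `probe` and `gene`
#'   (possibly several rows per probe).
#' @param q_cut significance threshold (default 0.05).
#' @return data.frame: `gene`, `significant`, `best_probe`, `min_q`,
#'   `direction` (of the best probe), `n_probes`.
#' @export
gene_level_summary <- function(de, probe_annot, q_cut = 0.05) {
  map <- probe_annot[probe_annot$probe %in% de$probe, c("probe", "gene")]
  map <- map[!is.na(map$gene), ]
  merged <- merge(map, de[, setdiff(colnames(de), "gene")], by = "probe")
  if (!nrow(merged))
    return(data.frame(gene = character(0), significant = logical(0),
                      best_probe = character(0), min_q = numeric(0),
                      direction = numeric(0), n_probes = integer(0),
                      stringsAsFactors = FALSE))
  # deterministic best-probe order: min q, then larger |t|, then probe id
  ord <- order(merged$gene, merged$q, -abs(merged$t), merged$probe)
  merged <- merged[ord, ]
  first <- !duplicated(merged$gene)
  out <- data.frame(gene = merged$gene[first],
                    significant = merged$q[first] <= q_cut,
                    best_probe = merged$probe[first],
                    min_q = merged$q[first],
                    direction = merged$direction[first],
                    n_probes = as.integer(table(merged$gene)[merged$gene[first]]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$gene), ]
}
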