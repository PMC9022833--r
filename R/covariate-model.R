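# Base biological covariates of every association model, in fixed order.
.base_covariates <- c("sex", "age", "lymphocytes", "monocytes",
                      "smoking", "log_bmi")

#' Build the base covariate design
#'
#' Intercept + sex + age + lymphocyte % + monocyte % + smoking status +
#' natural-log BMI. Cell fractions are used as given (percent or
#' proportion: this rescales the coefficient, not the test).
#'
#' @param annot sample annotation data.frame with columns `sex`, `age`,
#'   `lymphocytes`, `monocytes`, `smoking` and `bmi` (> 0).
#' @return Numeric design matrix, samples x 7, with column names.
#' @export
base_design <- function(annot) {
  need <- c("sex", "age", "lymphocytes", "monocytes", "smoking", "bmi")
  miss <- setdiff(need, colnames(annot))
  if (length(miss))
    stop("base_design: annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (any(annot$bmi <= 0)) stop("base_design: BMI must be > 0")
  X <- cbind("(Intercept)" = 1, sex = as.numeric(annot$sex),
             age = annot$age, lymphocytes = annot$lymphocytes,
             monocytes = annot$monocytes, smoking = as.numeric(annot$smoking),
             log_bmi = log(annot$bmi))
  rownames(X) <- rownames(annot)
  X
}

#' Screen candidate adjustment substances by prevalence
#'
#' Returns the substances taken by strictly more than `min_prevalence` of
#' the samples, sorted by descending prevalence. These are the candidates
#' for the polymedication adjustment model.
#'
#' @param med samples x substances 0/1 matrix.
#' @param min_prevalence strict prevalence threshold (default 0.05).
#' @return Character vector of labels (possibly empty).
#' @export
candidate_substances <- function(med, min_prevalence = 0.05) {
  if (ncol(med) == 0) return(character(0))
  prev <- colMeans(med)
  keep <- prev > min_prevalence
  names(sort(prev[keep], decreasing = TRUE))
}

#' Select the polymedication adjustment substances
#'
#' For each candidate, fits per-probe linear models with the base
#' covariates plus that candidate alone, moderates the variances, and
#' BH-adjusts the candidate's p-values across probes. Candidates with at
#' least one probe at q <= `fdr` enter the adjustment model. VIFs of the
#' final design are computed and flagged (never auto-dropped) when > 5.
#'
#' @param expr preprocessed [expression_matrix()] (log2 scale) or numeric
#'   matrix.
#' @param annot sample annotation (see [base_design()]).
#' @param med samples x substances 0/1 matrix.
#' @param candidates character vector of candidate labels (default: the
#'   prevalence screen at 5%).
#' @param fdr per-substance FDR level for the selection (default 0.05).
#' @return An `adjustment_model`: list with `base_covariates`,
#'   `substances` (selected labels, candidate order), `selection`
#'   (data.frame: substance, n_users, n_significant, min_q, selected) and
#'   `vif` (data.frame for the final design).
#' @export
select_adjustment_substances <- function(expr, annot, med,
                                         candidates = candidate_substances(med),
                                         fdr = 0.05) {
  y <- .expr_values(expr)
  X0 <- base_design(annot)
  sel <- data.frame(substance = character(0), n_users = integer(0),
                    n_significant = integer(0), min_q = numeric(0),
                    selected = logical(0), stringsAsFactors = FALSE)
  chosen <- character(0)
  for (lab in candidates) {
    drug <- as.numeric(med[, lab])
    if (stats::var(drug) == 0) {
      warning("select_adjustment_substances: '", lab,
              "' constant within analysis samples; skipped")
      next
    }
    X <- cbind(X0, drug = drug)
    fit <- fit_linear_models(y, X)
    mod <- moderate_variances(fit, coef = "drug")
    q <- bh_adjust(mod$p)
    nsig <- sum(q <= fdr)
    sel <- rbind(sel, data.frame(substance = lab, n_users = sum(drug),
                                 n_significant = nsig, min_q = min(q),
                                 selected = nsig >= 1,
                                 stringsAsFactors = FALSE))
    if (nsig >= 1) chosen <- c(chosen, lab)
  }
  X_final <- X0
  if (length(chosen)) {
    X_final <- cbind(X0, med[, chosen, drop = FALSE])
  }
  v <- vif(X_final)
  if (any(v$flagged, na.rm = TRUE) || any(v$vif > 5, na.rm = TRUE))
    warning("select_adjustment_substances: VIF > 5 for: ",
            paste(v$column[v$flagged | v$vif > 5], collapse = ", "))
  structure(list(base_covariates = .base_covariates, substances = chosen,
                 selection = sel, vif = v),
            class = "adjustment_model")
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat(sprintf("Polymedication adjustment model: %d base covariates + %d substance(s)\n",
              length(x$base_covariates), length(x$substances)))
  if (length(x$substances))
    cat("  substances:", paste(x$substances, collapse = ", "), "\n")
  invisible(x)
}

#' Variance inflation factors of a design matrix
#'
#' For each non-intercept column, VIF = 1 / (1 - R^2) where R^2 comes
#' from regressing that column (with intercept) on all other columns.
#' Computed via the inverse of the correlation matrix, with a per-column
#' regression fallback near singularity; a perfectly collinear column is
#' reported as infinite with a flag rather than an error.
#'
#' @param design samples x columns numeric matrix; an all-ones intercept
#'   column (if present) is excluded from the report.
#' @return data.frame with columns `column`, `vif`, `flagged`.
#' @export
vif <- function(design) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("V", seq_len(ncol(design)))
  const <- apply(design, 2, function(x) stats::var(x) == 0)
  cols <- colnames(design)[!const]
  if (nrow(design) <= length(cols))
    stop("vif: need more samples than (non-constant) columns")
  Xc <- design[, cols, drop = FALSE]
  if (length(cols) < 2)
    return(data.frame(column = cols, vif = rep(1, length(cols)),
                      flagged = FALSE, stringsAsFactors = FALSE))
  R <- stats::cor(Xc)
  v <- rep(NA_real_, length(cols))
  ok <- rcond(R) > 1e-12
  if (ok) v <- diag(solve(R))
  # fallback (or verification) per column when the correlation matrix is
  # (near-)singular
  if (!ok || any(v > 1e10)) {
    for (j in seq_along(cols)) {
      others <- cbind(1, Xc[, -j, drop = FALSE])
      res <- stats::lm.fit(others, Xc[, j])$residuals
      tot <- sum((Xc[, j] - mean(Xc[, j]))^2)
      r2 <- 1 - sum(res^2) / tot
      v[j] <- if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    }
  }
  data.frame(column = cols, vif = v, flagged = !is.finite(v),
             stringsAsFactors = FALSE)
}

#' Pairwise odds-ratio screen of the adjustment model
#'
#' Before testing a substance, each drug in the adjustment model is
#' cross-tabulated with it; drugs with an extreme pairwise odds ratio
#' (OR < `lo` or OR > `hi`) are dropped from the adjustment model for
#' this test to avoid collinearity. The tested substance is removed from
#' the adjustment list first (a variable cannot adjust for itself). Zero
#' cells are handled by the Haldane-Anscombe +0.5 correction on all
#' cells.
#'
#' @param med samples x substances 0/1 matrix.
#' @param tested label of the substance about to be tested.
#' @param adjustment character vector of adjustment-model substance
#'   labels.
#' @param lo,hi odds-ratio bounds (defaults 0.125 and 8).
#' @return List with `kept`, `dropped` (label vectors) and `report`
#'   (data.frame: substance, a, b, c, d, odds_ratio, dropped).
#' @export
pairwise_or_screen <- function(med, tested, adjustment,
                               lo = 0.125, hi = 8) {
  if (!tested %in% colnames(med))
    stop("pairwise_or_screen: tested substance '", tested,
         "' absent from the medication table")
  adjustment <- setdiff(adjustment, tested)
  miss <- setdiff(adjustment, colnames(med))
  if (length(miss))
    stop("pairwise_or_screen: adjustment substance(s) absent: ",
         paste(miss, collapse = ", "))
  x <- med[, tested]
  rows <- lapply(adjustment, function(lab) {
    z <- med[, lab]
    a <- sum(x == 1 & z == 1); b <- sum(x == 1 & z == 0)
    cc <- sum(x == 0 & z == 1); d <- sum(x == 0 & z == 0)
    or <- odds_ratio_2x2(a, b, cc, d)
    data.frame(substance = lab, a = a, b = b, c = cc, d = d,
               odds_ratio = or, dropped = or < lo || or > hi,
               stringsAsFactors = FALSE)
  })
  report <- if (length(rows)) do.call(rbind, rows)
  else data.frame(substance = character(0), a = integer(0), b = integer(0),
                  c = integer(0), d = integer(0), odds_ratio = numeric(0),
                  dropped = logical(0), stringsAsFactors = FALSE)
  list(kept = report$substance[!report$dropped],
       dropped = report$substance[report$dropped],
       report = report)
}

#' Odds ratio of a 2x2 table with zero-cell correction
#'
#' OR = (a d) / (b c); when any cell is zero, 0.5 is added to all four
#' cells (Haldane-Anscombe) so the ratio stays finite and the screening
#' rule stays total.
#'
#' @param a,b,c,d cell counts: a = both, b = first only, c = second only,
#'   d = neither.
#' @return The (corrected) odds ratio.
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}
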