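test_that("per-probe OLS matches the normal-equation oracle and special cases", {
  set.seed(30)
  n <- 60L
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.3))
  colnames(X) <- c("(Intercept)", "x", "d")
  y <- matrix(rnorm(100 * n), 100, n,
              dimnames = list(sprintf("P%03d", 1:100), sprintf("S%03d", 1:n)))
  fit <- fit_linear_models(y, X)
  expect_equal(unname(coef(fit)), unname(ols_oracle(y, X)), tolerance = 1e-10)
  expect_identical(fit$df_residual, n - 3L)
  # residual variance matches lm on a probe
  l1 <- lm(y[5, ] ~ X[, 2] + X[, 3])
  expect_equal(fit$sigma2[[5]], summary(l1)$sigma^2, tolerance = 1e-10)
  # a probe equal to a design column is fit exactly
  y2 <- rbind(y, noise_free = X[, 2])
  fit2 <- fit_linear_models(y2, X)
  expect_equal(unname(coef(fit2)["noise_free", ]), c(0, 1, 0), tolerance = 1e-10)
  expect_lt(fit2$sigma2[["noise_free"]], 1e-20)
  # intercept-only design: mean and variance
  fit3 <- fit_linear_models(y, matrix(1, n, 1))
  expect_equal(unname(coef(fit3)[, 1]), unname(rowMeans(y)), tolerance = 1e-12)
  expect_equal(unname(fit3$sigma2), unname(apply(y, 1, var)), tolerance = 1e-12)
  # rank-deficient design names the dependent column
  Xbad <- cbind(X, dup = X[, "x"])
  expect_error(fit_linear_models(y, Xbad), "dup")
})

test_that("variance moderation collapses correctly in its limits", {
  # identical residual variances: no excess spread, d0 = Inf
  fit <- make_fit(rep(2, 50), df = 10, beta = rnorm(50))
  mod <- moderate_variances(fit)
  expect_identical(mod$d0, Inf)
  expect_equal(mod$s2_post, rep(mod$s02, 50))
  expect_equal(mod$p, 2 * pnorm(-abs(fit$coefficients[, 1] / sqrt(mod$s02))),
               tolerance = 1e-6)
  # moderation disabled: ordinary t with d degrees of freedom
  set.seed(31)
  s2 <- rchisq(50, 8) / 8
  fit2 <- make_fit(s2, df = 8, beta = rnorm(50))
  raw <- moderate_variances(fit2, moderation = FALSE)
  expect_equal(raw$t, fit2$coefficients[, 1] / sqrt(s2))
  expect_equal(raw$p, 2 * pt(-abs(raw$t), 8))
  expect_error(moderate_variances(make_fit(rep(1, 5), 4)), ">= 10 probes")
  expect_error(moderate_variances(make_fit(rep(0, 20), 4)), "zero")
})

test_that("moderation recovers known prior hyperparameters", {
  # s2 ~ s02 * (d0/chisq_d0) * chisq_d / d with d0 = 4, s02 = 2
  set.seed(32)
  G <- 5000; d0 <- 4; s02 <- 2; d <- 10
  sigma2 <- s02 * d0 / rchisq(G, d0)
  s2 <- sigma2 * rchisq(G, d) / d
  mod <- moderate_variances(make_fit(s2, df = d))
  expect_lt(abs(mod$d0 - d0) / d0, 0.25)
  expect_lt(abs(mod$s02 - s02) / s02, 0.10)
})

test_that("moderation agrees with the reference empirical-Bayes implementation", {
  set.seed(33)
  s2 <- 1.5 * 4 / rchisq(2000, 4) * rchisq(2000, 12) / 12
  fit <- make_fit(s2, df = 12, beta = rnorm(2000), v = 0.04)
  mod <- moderate_variances(fit)
  ref <- limma::squeezeVar(s2, df = 12)
  expect_equal(mod$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(mod$s02, ref$var.prior, tolerance = 1e-6)
  expect_equal(mod$s2_post, ref$var.post, tolerance = 1e-8)
})

test_that("posterior variances increase strictly with the sample variances", {
  set.seed(34)
  s2 <- sort(rchisq(100, 6))
  mod <- moderate_variances(make_fit(s2, df = 6))
  expect_true(all(diff(mod$s2_post) > 0))
  expect_true(all(mod$s2_post >= pmin(s2, mod$s02) - 1e-12))
  expect_true(all(mod$s2_post <= pmax(s2, mod$s02) + 1e-12))
})

test_that("BH adjustment reproduces the step-up formula and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(35)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
  # monotone: pointwise larger p gives pointwise >= q
  p <- runif(20); p2 <- pmin(p + runif(20, 0, 0.2), 1)
  expect_true(all(bh_adjust(p2) >= bh_adjust(p) - 1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "finite")
})

test_that("test_substance finds planted effects and guards degenerate designs", {
  ch <- small_cohort(n = 1200, probes = 300, n_affected = 5, seed = 36,
                     beta = c(0.45, 0.45))
  expr <- log2_transform(quantile_normalize(ch$expr))
  de <- test_substance(expr, ch$annot, ch$med, "drugA",
                       probe_annot = ch$probe_annot)
  expect_s3_class(de, "de_result")
  m <- match(ch$truth$effects$probe, de$probe)
  expect_gte(sum(de$q[m] <= 0.05), 4)   # >= 4 of the 5 planted probes
  expect_true(all(de$direction == sign(de$beta)))
  expect_true(all(de$q >= de$p - 1e-15))
  expect_false(anyNA(de$gene))
  # substance identical to an adjustment drug is screened out, fit proceeds
  med2 <- cbind(ch$med, clone = ch$med[, "drugA"])
  model <- structure(list(base_covariates = pharmtx:::.base_covariates,
                          substances = "clone"), class = "adjustment_model")
  de2 <- test_substance(expr, ch$annot, med2, "drugA", model = model)
  expect_identical(attr(de2, "adjustment_dropped"), "clone")
  expect_equal(de2$beta, de$beta, tolerance = 1e-10)
  # too few users: skipped, not an error
  med3 <- ch$med; med3[, 1] <- c(rep(1L, 10), rep(0L, 1190))
  expect_message(res <- test_substance(expr, ch$annot, med3, "drugA"),
                 "skipped")
  expect_null(res)
})

test_that("gene-level summary applies the one-probe rule with fan-out", {
  de <- structure(data.frame(probe = c("p1", "p2", "p3", "p4"),
                             gene = NA_character_,
                             beta = c(0.5, -0.2, 0.1, 0.3),
                             se = 0.1, t = c(5, -2, 1, 3),
                             p = c(1e-4, 0.1, 0.6, 0.01),
                             q = c(0.04, 0.2, 0.8, 0.06),
                             direction = c(1, -1, 1, 1),
                             stringsAsFactors = FALSE),
                  class = c("de_result", "data.frame"), substance = "s")
  annot <- data.frame(probe = c("p1", "p2", "p3", "p4", "p4"),
                      gene = c("gA", "gA", "gB", "gC", "gD"),
                      stringsAsFactors = FALSE)
  gs <- gene_level_summary(de, annot, q_cut = 0.05)
  expect_identical(gs$gene, c("gA", "gB", "gC", "gD"))
  # gA: probes q = 0.04, 0.2 -> significant, best probe p1
  expect_true(gs$significant[gs$gene == "gA"])
  expect_identical(gs$best_probe[gs$gene == "gA"], "p1")
  # gB: q = 0.8 only -> not significant
  expect_false(gs$significant[gs$gene == "gB"])
  # p4 maps to both gC and gD: both inherit it
  expect_identical(gs$best_probe[gs$gene %in% c("gC", "gD")], c("p4", "p4"))
  # q ties broken by larger |t|
  de$q <- rep(0.04, 4); de$t <- c(2, -6, 1, 3)
  gs2 <- gene_level_summary(de, annot)
  expect_identical(gs2$best_probe[gs2$gene == "gA"], "p2")
})
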