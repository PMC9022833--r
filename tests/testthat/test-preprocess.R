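test_that("detection filter keeps probes at the inclusive 5% boundary", {
  set.seed(1)
  detp <- matrix(runif(3 * 100, 0.5, 1), 3, 100)
  detp[1, 1:5] <- 0.01    # detected in exactly 5 of 100 samples
  detp[2, 1:4] <- 0.01    # detected in 4 of 100
  detp[3, ] <- 0.01       # detected everywhere
  expr <- make_expr(matrix(100, 3, 100), detection_p = detp)
  mask <- detection_filter(expr, alpha = 0.05, min_fraction = 0.05)
  expect_identical(mask$keep, c(TRUE, FALSE, TRUE))
  expect_identical(mask$reason[2], "not_expressed")
  expect_error(detection_filter(make_expr(matrix(1, 2, 3))), "detection")
})

test_that("detection filter removes unexpressed probes at the binomial rate", {
  # uniform detection p-values put the keep threshold exactly at the
  # binomial mean, so about half of truly unexpressed probes survive;
  # expressed probes (Beta(0.5, 20)) survive essentially always
  set.seed(2)
  n <- 500; g <- 400
  detp <- rbind(matrix(runif(g / 2 * n), g / 2, n),
                matrix(rbeta(g / 2 * n, 0.5, 20), g / 2, n))
  expr <- make_expr(matrix(100, g, n), detection_p = detp)
  mask <- detection_filter(expr)
  removed_null <- mean(!mask$keep[1:(g / 2)])
  expected <- stats::pbinom(ceiling(0.05 * n) - 1, n, 0.05)  # P(count < 25)
  expect_lt(abs(removed_null - expected), 0.1)
  expect_true(all(mask$keep[(g / 2 + 1):g]))
})

test_that("quantile normalization equalizes sample distributions", {
  # mean-of-order-statistics example: A=(1,3), B=(2,4) -> both (1.5, 3.5)
  expr <- make_expr(matrix(c(1, 3, 2, 4), 2, 2))
  qn <- quantile_normalize(expr)
  expect_equal(unname(qn$values), matrix(c(1.5, 3.5, 1.5, 3.5), 2, 2))
  # identical columns are a fixed point
  expr2 <- make_expr(matrix(c(5, 1, 9), 3, 4))
  expect_equal(quantile_normalize(expr2)$values, expr2$values)
  # random matrix: all columns share the same sorted values afterwards
  set.seed(3)
  expr3 <- make_expr(matrix(rlnorm(50 * 10), 50, 10))
  qn3 <- quantile_normalize(expr3)$values
  sorted <- apply(qn3, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # total sum equals the sum of mean order statistics times n_samples
  expect_equal(sum(qn3), sum(rowMeans(apply(expr3$values, 2, sort))) * 10)
  expect_error(quantile_normalize(make_expr(matrix(1:5, 5, 1))), "2 samples")
})

test_that("log2 transform is exact and guards against non-positive values", {
  expr <- make_expr(matrix(c(8, 1, 2, 1024), 2, 2))
  lg <- log2_transform(expr)
  expect_equal(unname(lg$values), matrix(c(3, 0, 1, 10), 2, 2))
  expect_identical(lg$scale, "log2")
  set.seed(4)
  x <- matrix(2^rnorm(20), 4, 5)
  expect_equal(log2_transform(make_expr(x))$values,
               make_expr(log2(x))$values, tolerance = 1e-12)
  bad <- make_expr(matrix(c(1, -2, 3, 4), 2, 2))
  expect_error(log2_transform(bad), "non-positive")
})

test_that("Mahalanobis distances reduce to the familiar special cases", {
  set.seed(5)
  # identity covariance: distances equal Euclidean distances to the mean
  x <- matrix(rnorm(4000), 1000, 4)
  x <- scale(x) %*% diag(4)   # decorrelate approximately
  rownames(x) <- sprintf("S%04d", 1:1000)
  mask <- mahalanobis_qc(x)
  eu <- sqrt(rowSums(scale(x, scale = FALSE)^2))
  # sample covariance is close to identity, not exact: loose tolerance
  expect_lt(max(abs(mask$score - eu)), 0.5)
  # single feature: |x - mean| / sd
  x1 <- matrix(rnorm(100), 100, 1, dimnames = list(sprintf("S%03d", 1:100), "f"))
  m1 <- mahalanobis_qc(x1)
  expect_equal(m1$score, abs(x1[, 1] - mean(x1)) / sd(x1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("Mahalanobis distances match the quadratic-form oracle and are affine invariant", {
  set.seed(6)
  x <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(sprintf("S%03d", 1:200), NULL))
  mask <- mahalanobis_qc(x)
  expect_equal(mask$score, mahalanobis_oracle(x), tolerance = 1e-10,
               ignore_attr = TRUE)
  A <- matrix(rnorm(25), 5, 5) + diag(5)
  y <- x %*% A + matrix(rnorm(5), 200, 5, byrow = TRUE)
  rownames(y) <- rownames(x)
  expect_lt(max(abs(mahalanobis_qc(y)$score - mask$score)), 1e-8)
})

test_that("null Mahalanobis squared distances follow chi-square", {
  set.seed(7)
  p <- 5
  x <- MASS::mvrnorm(2000, rep(0, p), diag(p))
  rownames(x) <- sprintf("S%04d", 1:2000)
  d2 <- mahalanobis_qc(x)$score^2
  expect_gt(stats::ks.test(d2, "pchisq", df = p)$p.value, 0.01)
})

test_that("batch adjustment removes planted location shifts", {
  set.seed(10)
  g <- 300; n <- 1000
  batch <- factor(rep(1:2, each = n / 2))
  y <- matrix(rnorm(g * n), g, n) + 8
  dimnames(y) <- list(sprintf("P%03d", 1:g), sprintf("S%04d", 1:n))
  y[, batch == 2] <- y[, batch == 2] + 1           # pure +1 shift
  expr_shift <- make_expr(y, scale = "log2")
  pre <- batch_anova_check(expr_shift, batch)
  adj <- combat_adjust(expr_shift, batch)
  post <- batch_anova_check(adj$expr, batch)
  b2 <- batch == 2
  mean_diff <- rowMeans(adj$expr$values[, b2]) - rowMeans(adj$expr$values[, !b2])
  expect_lt(mean(abs(mean_diff)), 0.05)
  expect_gt(pre$frac_significant, 0.5)
  expect_lte(post$frac_significant, 0.07)
})

test_that("batch adjustment rescales a planted scale factor", {
  set.seed(11)
  g <- 300; n <- 400
  batch <- factor(rep(1:2, each = n / 2))
  y <- matrix(rnorm(g * n), g, n)
  y[, batch == 2] <- y[, batch == 2] * 2
  y <- y + 8
  dimnames(y) <- list(sprintf("P%03d", 1:g), sprintf("S%03d", 1:n))
  adj <- combat_adjust(make_expr(y, scale = "log2"), batch)$expr$values
  ratio <- apply(adj[, batch == 2], 1, var) / apply(adj[, batch == 1], 1, var)
  med_ratio <- median(ratio)
  expect_gt(med_ratio, 0.8); expect_lt(med_ratio, 1.25)
})

test_that("batch adjustment is idempotent and a no-op for one batch", {
  ch <- small_cohort(n = 200, probes = 150, n_batches = 3, seed = 12)
  expr <- log2_transform(quantile_normalize(ch$expr))
  one <- combat_adjust(expr, rep(1, 200))
  expect_equal(one$expr$values, expr$values, tolerance = 1e-10)
  # re-adjustment is a strong contraction: after one pass the remaining
  # batch signal is dominated by moment-estimate noise, so a second pass
  # moves values by an order of magnitude less than the first
  adj1 <- combat_adjust(expr, ch$annot$batch)$expr
  adj2 <- combat_adjust(adj1, ch$annot$batch)$expr
  step1 <- mean(abs(adj1$values - expr$values))
  step2 <- mean(abs(adj2$values - adj1$values))
  expect_lt(step2, 0.15 * step1)
  expect_error(combat_adjust(expr, c(rep(1, 199), 2)), "single sample")
})

test_that("batch adjustment agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  ch <- small_cohort(n = 300, probes = 200, n_batches = 3, seed = 13)
  expr <- log2_transform(quantile_normalize(ch$expr))
  mine <- combat_adjust(expr, ch$annot$batch)$expr$values
  ref <- suppressMessages(
    sva::ComBat(expr$values, batch = ch$annot$batch, par.prior = TRUE,
                prior.plots = FALSE))
  expect_lt(max(abs(mine - ref)), 1e-6)
})

test_that("ANOVA check is calibrated under the null and runs at minimum batch size", {
  set.seed(14)
  y <- matrix(rnorm(500 * 120), 500, 120,
              dimnames = list(sprintf("P%03d", 1:500), sprintf("S%03d", 1:120)))
  chk <- batch_anova_check(y, rep(1:4, each = 30))
  expect_lt(abs(chk$frac_significant - 0.05), 0.04)
  expect_gt(stats::ks.test(chk$p, "punif")$p.value, 0.01)
  tiny <- batch_anova_check(y[, 1:4], c(1, 1, 2, 2))
  expect_length(tiny$p, 500)
})

test_that("Euclidean outlier filter flags gross expression outliers", {
  set.seed(15)
  y <- matrix(rnorm(200 * 100, sd = 1), 200, 100,
              dimnames = list(sprintf("P%03d", 1:200), sprintf("S%03d", 1:100)))
  # all samples identical: nothing removed, all distances zero
  same <- matrix(5, 50, 20,
                 dimnames = list(sprintf("P%03d", 1:50), sprintf("S%03d", 1:20)))
  m0 <- euclidean_outlier_filter(same)
  expect_true(all(m0$keep))
  expect_true(all(m0$score == 0))
  # one sample shifted far away is removed
  y[, 7] <- y[, 7] + 50
  mask <- euclidean_outlier_filter(y)
  expect_false(mask$keep[7])
  expect_identical(sum(!mask$keep), 1L)
  # trim = 0 equals the untrimmed-mean version
  y2 <- y[, -7]
  expect_equal(euclidean_outlier_filter(y2, trim = 0)$score,
               sqrt(colSums((y2 - rowMeans(y2))^2)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(euclidean_outlier_filter(y[, 1:5]), ">= 10 samples")
})
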