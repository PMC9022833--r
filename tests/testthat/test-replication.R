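fam <- function(p, dd, dr, probes = sprintf("p%d", seq_along(p))) {
  data.frame(probe = probes, p = p, direction_discovery = dd,
             direction_replication = dr, stringsAsFactors = FALSE)
}

test_that("hierarchical adjustment follows the hand-computed selection path", {
  # three families engineered so their min BH q-values are 0.001, 0.5, 0.9
  f1 <- fam(c(0.001, 0.012, 0.04), dd = c(1, 1, -1), dr = c(1, 1, 1))
  f2 <- fam(c(0.25, 0.9), dd = c(1, -1), dr = c(1, -1))
  f3 <- fam(0.9, dd = 1, dr = 1)
  res <- hierarchical_adjust(list(A = f1, B = f2, C = f3), q_level = 0.05)
  # family statistics: min q = (0.003, 0.5, 0.9); BH across -> (0.009, 0.75, 0.9)
  expect_equal(res$families$min_q, c(0.003, 0.5, 0.9))
  expect_equal(res$families$family_q, c(0.009, 0.75, 0.9))
  expect_identical(res$families$selected, c(TRUE, FALSE, FALSE))
  expect_identical(res$S, 1L)
  # selected family re-thresholded at 0.05 * 1/3
  qA <- bh_adjust(f1$p)   # 0.003, 0.018, 0.04
  expect_identical(res$probes$significant[1:3], qA <= 0.05 / 3)
  # only probe 1 passes 0.05/3; probe 3 is also direction-discordant
  expect_identical(res$probes$replicated[1:3], c(TRUE, FALSE, FALSE))
  # the family_bh variant keeps the within-family level at q_level
  res2 <- hierarchical_adjust(list(A = f1, B = f2, C = f3),
                              variant = "family_bh")
  expect_identical(res2$probes$significant[1:3], qA <= 0.05)
})

test_that("opposite effect directions never replicate", {
  f <- fam(c(1e-8, 1e-8), dd = c(1, -1), dr = c(-1, 1))
  res <- hierarchical_adjust(list(A = f))
  expect_true(res$families$selected[1])
  expect_identical(res$families$n_replicated, 0L)
  expect_true(all(res$probes$significant))
  expect_false(any(res$probes$replicated))
})

test_that("a q = 1 probe never changes which other probes replicate", {
  set.seed(40)
  f1 <- fam(runif(20, 0, 0.02), dd = rep(1, 20), dr = rep(1, 20))
  f2 <- fam(runif(10), dd = rep(1, 10), dr = rep(-1, 10))
  base <- hierarchical_adjust(list(A = f1, B = f2))
  f1b <- rbind(f1, fam(1, 1, 1, probes = "extra"))
  with_extra <- hierarchical_adjust(list(A = f1b, B = f2))
  keep <- with_extra$probes$probe != "extra"
  expect_identical(with_extra$probes$replicated[keep], base$probes$replicated)
})

test_that("nominal replication requires p <= 0.05 and concordant direction", {
  f <- fam(c(0.049, 0.049, 0.051), dd = c(1, 1, 1), dr = c(1, -1, 1))
  nr <- nominal_replication(list(A = f))
  expect_identical(nr$replicated_nominal, c(TRUE, FALSE, FALSE))
})

test_that("sign test matches the exact binomial enumeration", {
  expect_equal(sign_test(rep(1, 8), rep(1, 8)), 2 * 0.5^8)   # 0.0078125
  expect_equal(sign_test(rep(1, 8), rep(1, 8)), 0.0078125)
  expect_equal(sign_test(c(rep(1, 5), rep(-1, 5)), rep(1, 10)), 1)
  expect_equal(sign_test(rep(1, 6), rep(-1, 6)), 2 * 0.5^6)  # 0.03125
  set.seed(41)
  for (i in 1:15) {
    n <- sample(1:20, 1)
    s1 <- sample(c(-1, 1), n, replace = TRUE)
    s2 <- sample(c(-1, 1), n, replace = TRUE)
    expect_equal(sign_test(s1, s2), sign_test_oracle(sum(s1 == s2), n))
  }
  expect_error(sign_test(c(1, 1), 1), "equal length")
  expect_error(sign_test(c(1, 0), c(1, 1)), "signs")
})

test_that("two-cohort simulation replicates shared true effects", {
  cfg <- sim_config(n_samples = 1200, n_probes = 300, n_genes = 250,
                    substances = list(
                      substance_spec("drugA", 0.2, 8, c(0.5, 0.6)),
                      substance_spec("drugB", 0.15, 0, c(0, 0))),
                    seed = 42)
  disc <- run_discovery(generate_cohort(cfg, cohort = 1))
  repl <- run_replication(disc, generate_cohort(cfg, cohort = 2))
  famA <- repl$replication$families
  expect_true(famA$selected[famA$substance == "drugA"])
  probesA <- repl$replication$probes
  truth <- cfg$substances[[1]]
  true_probes <- generate_cohort(cfg)$truth$effects$probe
  repl_probes <- probesA$probe[probesA$replicated]
  expect_gte(length(intersect(repl_probes, true_probes)), 6)
  # flipping the replication drug coding flips directions, zeroing replication
  coh2 <- generate_cohort(cfg, cohort = 2)
  coh2$med[, "drugA"] <- 1L - coh2$med[, "drugA"]
  repl_flip <- run_replication(disc, coh2)
  pf <- repl_flip$replication$probes
  pf <- pf[pf$substance == "drugA", ]
  p0 <- probesA[probesA$substance == "drugA", ]
  expect_equal(pf$direction_replication[match(p0$probe, pf$probe)],
               -p0$direction_replication)
  expect_identical(sum(pf$replicated), 0L)
})

test_that("substances missing from the replication cohort are excluded with reasons", {
  cfg <- sim_config(n_samples = 800, n_probes = 250, n_genes = 200,
                    substances = list(substance_spec("drugA", 0.2, 6,
                                                     c(0.5, 0.6))),
                    seed = 43)
  disc <- run_discovery(generate_cohort(cfg, cohort = 1))
  coh2 <- generate_cohort(cfg, cohort = 2)
  med2 <- coh2$med; colnames(med2) <- "otherdrug"
  expr2 <- log2_transform(quantile_normalize(coh2$expr))
  expect_error(hierarchical_replication(disc$results, expr2, coh2$annot,
                                        med2, disc$model),
               "no substance")
  med3 <- cbind(coh2$med, rare = c(rep(1L, 5), rep(0L, 795)))
  res <- hierarchical_replication(disc$results, expr2, coh2$annot, med3,
                                  disc$model)
  expect_s3_class(res, "replication_result")
})
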