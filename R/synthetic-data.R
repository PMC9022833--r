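#' Specify one simulated active substance
#'
#' Describes the marginal intake prevalence of an active substance, the
#' probe subset it perturbs, and an optional co-medication partner whose
#' joint intake follows a prescribed odds ratio (the pairwise structure
#' typical of polymedication, e.g. an antihypertensive co-prescribed with
#' a statin).
#'
#' @param label substance label (ATC level-5 style, e.g. `"C07AB02"` or a
#'   substance name).
#' @param prevalence marginal intake probability, strictly in (0, 1).
#' @param n_affected_probes number of expressed probes that receive a
#'   planted expression effect for this substance.
#' @param effect_distribution numeric length-2 `(low, high)`: planted
#'   effects are drawn uniformly from this range, in log2 units.
#' @param comedication_partner optional label of another substance; joint
#'   intake of the pair is generated with the odds ratio below.
#' @param comedication_log_or log odds ratio of joint intake with the
#'   partner (ignored when no partner is declared).
#' @param down_fraction fraction of affected probes whose planted effect
#'   has its sign flipped to negative (default 0.5: balanced up/down
#'   regulation, as is typical of drug signatures; magnitudes still come
#'   from `effect_distribution`). Set to 0 to use the distribution's
#'   signs as given.
#'
#' @return A `substance_spec` list.
#' @export
substance_spec <- function(label, prevalence, n_affected_probes = 0,
                           effect_distribution = c(0, 0),
                           comedication_partner = NULL,
                           comedication_log_or = 0,
                           down_fraction = 0.5) {
  if (!is.character(label) || length(label) != 1 || !nzchar(label))
    stop("substance_spec: 'label' must be a non-empty string")
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("substance_spec: 'prevalence' must lie strictly in (0, 1)")
  if (n_affected_probes < 0)
    stop("substance_spec: 'n_affected_probes' must be >= 0")
  if (length(effect_distribution) != 2 ||
      effect_distribution[1] > effect_distribution[2])
    stop("substance_spec: 'effect_distribution' must be (low, high) with low <= high")
  if (down_fraction < 0 || down_fraction > 1)
    stop("substance_spec: 'down_fraction' must lie in [0, 1]")
  structure(list(label = label, prevalence = prevalence,
                 n_affected_probes = as.integer(n_affected_probes),
                 effect_distribution = as.numeric(effect_distribution),
                 comedication_partner = comedication_partner,
                 comedication_log_or = comedication_log_or,
                 down_fraction = down_fraction),
            class = "substance_spec")
}

#' Simulation configuration for a synthetic expression cohort
#'
#' Bundles all knobs of the cohort generator. Defaults emulate a
#' population-based microarray study: ~log-normal raw intensities, additive
#' covariate and drug effects on probe subsets (log2 scale), per-chip batch
#' location/scale effects, correlated co-medication, multi-probe genes and
#' a configurable fraction of QC-failing samples.
#'
#' @param n_samples,n_probes,n_genes,n_batches counts (all >= 1;
#'   `n_genes <= n_probes`; each batch must receive at least two samples).
#' @param substances list of [substance_spec()] objects.
#' @param covariate_effect_sizes named numeric vector of per-unit log2
#'   effects for the base covariates `sex`, `age`, `lymphocytes`,
#'   `monocytes`, `smoking`, `log_bmi`; each covariate perturbs a random
#'   `covariate_affected_fraction` of probes.
#' @param covariate_affected_fraction fraction of probes perturbed by each
#'   covariate.
#' @param noise_sd residual SD in log2 units.
#' @param batch_location_sd SD of per-batch per-probe location shifts
#'   (log2 units).
#' @param batch_scale_shape shape of the inverse-gamma distribution of
#'   per-batch per-probe noise variance multipliers (mean fixed at 1);
#'   larger means weaker scale effects. Must be > 2 so the variance of the
#'   multiplier is finite.
#' @param qc_outlier_fraction fraction of samples planted as QC failures
#'   in the QC-feature table, in `[0, 0.25)`.
#' @param expressed_fraction fraction of probes that are truly expressed
#'   (small detection p-values); unexpressed probes get uniform detection
#'   p-values.
#' @param control_fraction fraction of samples forced to take no
#'   medication at all (the control group); marginal prevalences are
#'   preserved by rescaling intake among the remaining samples.
#' @param seed integer seed; all outputs are a deterministic function of
#'   the configuration including the seed.
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 3000, n_probes = 2000, n_genes = 1600,
                       n_batches = 1, substances = list(),
                       covariate_effect_sizes = c(sex = 0.2, age = 0.005,
                                                  lymphocytes = 0.015,
                                                  monocytes = 0.03,
                                                  smoking = 0.15,
                                                  log_bmi = 0.3),
                       covariate_affected_fraction = 0.1,
                       noise_sd = 1, batch_location_sd = 0.3,
                       batch_scale_shape = 50, qc_outlier_fraction = 0,
                       expressed_fraction = 0.9, control_fraction = 0,
                       seed = 1L) {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x))
      stop(sprintf("sim_config: '%s' must be a count >= 1", nm))
  }
  chk_count(n_samples, "n_samples"); chk_count(n_probes, "n_probes")
  chk_count(n_genes, "n_genes"); chk_count(n_batches, "n_batches")
  if (n_genes > n_probes) stop("sim_config: 'n_genes' must be <= 'n_probes'")
  if (n_samples < 2 * n_batches)
    stop("sim_config: 'n_batches' too large: each batch needs at least two samples")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("sim_config: 'noise_sd' must be > 0")
  if (batch_scale_shape <= 2)
    stop("sim_config: 'batch_scale_shape' must be > 2")
  if (qc_outlier_fraction < 0 || qc_outlier_fraction >= 0.25)
    stop("sim_config: 'qc_outlier_fraction' must lie in [0, 0.25)")
  if (expressed_fraction <= 0 || expressed_fraction > 1)
    stop("sim_config: 'expressed_fraction' must lie in (0, 1]")
  if (control_fraction < 0 || control_fraction >= 1)
    stop("sim_config: 'control_fraction' must lie in [0, 1)")
  for (s in substances)
    if (!inherits(s, "substance_spec"))
      stop("sim_config: 'substances' must be a list of substance_spec objects")
  labs <- vapply(substances, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("sim_config: duplicate substance labels")
  structure(list(n_samples = as.integer(n_samples),
                 n_probes = as.integer(n_probes),
                 n_genes = as.integer(n_genes),
                 n_batches = as.integer(n_batches),
                 substances = substances,
                 covariate_effect_sizes = covariate_effect_sizes,
                 covariate_affected_fraction = covariate_affected_fraction,
                 noise_sd = noise_sd,
                 batch_location_sd = batch_location_sd,
                 batch_scale_shape = batch_scale_shape,
                 qc_outlier_fraction = qc_outlier_fraction,
                 expressed_fraction = expressed_fraction,
                 control_fraction = control_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Truncated normal by rejection; fine for the mild truncations used here.
.rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Simulate base covariates for a cohort
#'
#' Draws sex ~ Bernoulli(0.5), age ~ Normal(60, 12) truncated to [18, 90],
#' lymphocyte and monocyte percentages and BMI from truncated normals with
#' moments typical of an adult population cohort, smoking ~ Bernoulli(0.2),
#' and assigns samples to expression chips (batches) in near-equal blocks.
#'
#' @param n_samples number of samples.
#' @param n_batches number of chips/batches.
#' @param seed integer seed.
#' @return data.frame with rownames `S0001`, ... and columns `sex`, `age`,
#'   `lymphocytes`, `monocytes`, `smoking`, `bmi` and factor `batch`.
#' @export
simulate_covariates <- function(n_samples, n_batches = 1, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("S%04d", seq_len(n_samples))
  ann <- data.frame(
    sex = stats::rbinom(n_samples, 1, 0.5),
    age = .rtnorm(n_samples, 60, 12, 18, 90),
    lymphocytes = .rtnorm(n_samples, 30, 7.9, 2, 70),
    monocytes = .rtnorm(n_samples, 8.2, 2.1, 0.5, 25),
    smoking = stats::rbinom(n_samples, 1, 0.2),
    bmi = .rtnorm(n_samples, 27.9, 4.8, 15, 55),
    row.names = ids)
  ann$batch <- factor(rep(seq_len(n_batches), length.out = n_samples))
  ann
}

#' Assign binary medication intake to samples
#'
#' Substances without a declared partner are independent Bernoulli draws
#' at their prevalence. A substance with a `comedication_partner` is drawn
#' jointly with its partner from the 2x2 distribution that has the two
#' marginal prevalences and the requested odds ratio (the Plackett
#' construction; no higher-order interactions). A `control_fraction` of
#' samples is forced to zero intake; marginal prevalences are preserved by
#' rescaling intake probability among the remaining samples.
#'
#' @param covariates sample annotation data.frame (rownames = sample ids);
#'   only its rownames/row count are used.
#' @param specs non-empty list of [substance_spec()] objects.
#' @param seed integer seed.
#' @param control_fraction fraction of samples with zero substances.
#' @return Integer 0/1 matrix, samples x substances, with dimnames.
#' @export
assign_medication <- function(covariates, specs, seed = 1L,
                              control_fraction = 0) {
  if (!length(specs)) stop("assign_medication: 'specs' must be non-empty")
  n <- nrow(covariates)
  ids <- rownames(covariates)
  labs <- vapply(specs, `[[`, "", "label")
  names(specs) <- labs
  set.seed(seed)

  controls <- rep(FALSE, n)
  if (control_fraction > 0)
    controls[sample.int(n, round(control_fraction * n))] <- TRUE
  n_act <- sum(!controls)
  scale_p <- function(p) {
    p_eff <- p / (1 - control_fraction)
    if (p_eff >= 1)
      stop("assign_medication: prevalence ", p,
           " not attainable with control_fraction ", control_fraction)
    p_eff
  }

  med <- matrix(0L, n, length(labs), dimnames = list(ids, labs))

  # resolve partner pairs (each substance in at most one pair)
  pairs <- list()
  in_pair <- character(0)
  for (s in specs) {
    p <- s$comedication_partner
    if (is.null(p)) next
    if (!p %in% labs)
      stop("assign_medication: partner '", p, "' of '", s$label,
           "' not among the specified substances")
    key <- paste(sort(c(s$label, p)), collapse = "\r")
    if (key %in% names(pairs)) next
    if (s$label %in% in_pair || p %in% in_pair)
      stop("assign_medication: substance in more than one co-medication pair")
    pairs[[key]] <- list(a = s$label, b = p, log_or = s$comedication_log_or)
    in_pair <- c(in_pair, s$label, p)
  }

  draw_idx <- which(!controls)
  for (pr in pairs) {
    p1 <- scale_p(specs[[pr$a]]$prevalence)
    p2 <- scale_p(specs[[pr$b]]$prevalence)
    cells <- .plackett_cells(p1, p2, pr$log_or)
    cat_draw <- sample.int(4, n_act, replace = TRUE, prob = cells)
    # cells order: (1,1), (1,0), (0,1), (0,0)
    med[draw_idx, pr$a] <- as.integer(cat_draw %in% c(1L, 2L))
    med[draw_idx, pr$b] <- as.integer(cat_draw %in% c(1L, 3L))
  }
  for (lab in setdiff(labs, in_pair))
    med[draw_idx, lab] <- stats::rbinom(n_act, 1, scale_p(specs[[lab]]$prevalence))
  med
}

# 2x2 cell probabilities ((1,1),(1,0),(0,1),(0,0)) with marginals p1, p2
# and odds ratio exp(log_or): the Plackett solution. Degenerate joints
# (any zero cell, e.g. infinite OR) are rejected.
.plackett_cells <- function(p1, p2, log_or) {
  psi <- exp(log_or)
  if (!is.finite(psi) || psi <= 0)
    stop("assign_medication: no joint intake distribution exists for ",
         "log odds ratio ", log_or)
  if (abs(psi - 1) < 1e-12) {
    p11 <- p1 * p2
  } else {
    S <- 1 + (p1 + p2) * (psi - 1)
    p11 <- (S - sqrt(S^2 - 4 * psi * (psi - 1) * p1 * p2)) / (2 * (psi - 1))
  }
  cells <- c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
  if (any(cells <= 1e-12))
    stop("assign_medication: no joint intake distribution exists ",
         "(an implied cell probability is zero; marginals ", p1, "/", p2,
         " with log OR ", log_or, ")")
  cells
}

#' Simulate per-sample array QC features
#'
#' Emulates the continuous chip-level quality features of an expression
#' BeadChip run (perfect-match and mismatch control signal, concentration
#' controls, negative-control mean, housekeeping-gene mean, number of
#' expressed genes, biotin-control signal, mean Euclidean distance to
#' other samples). Inliers come from one multivariate normal with
#' exchangeable correlation 0.3; planted outliers are shifted by at least
#' 6 marginal SDs on one to three randomly chosen features.
#'
#' @param n_samples number of samples.
#' @param outlier_fraction fraction of planted failures, in `[0, 0.25)`.
#' @param seed integer seed.
#' @return A list with `features` (samples x 8 numeric matrix) and
#'   `outlier` (named logical vector of planted flags).
#' @export
generate_qc_features <- function(n_samples, outlier_fraction = 0, seed = 1L) {
  if (outlier_fraction < 0 || outlier_fraction >= 0.25)
    stop("generate_qc_features: 'outlier_fraction' must lie in [0, 0.25)")
  set.seed(seed)
  feats <- c("pm_control", "mm_control", "conc_control", "neg_control_mean",
             "housekeeping_mean", "n_expressed", "biotin_signal", "mean_dist")
  mu <- c(12000, 300, 5000, 120, 9000, 15000, 20000, 40)
  sd <- mu * 0.1
  p <- length(feats)
  Sigma <- (diag(1 - 0.3, p) + 0.3) * tcrossprod(sd)
  x <- MASS::mvrnorm(n_samples, mu = mu, Sigma = Sigma)
  ids <- sprintf("S%04d", seq_len(n_samples))
  dimnames(x) <- list(ids, feats)
  out <- rep(FALSE, n_samples); names(out) <- ids
  n_out <- round(outlier_fraction * n_samples)
  if (n_out > 0) {
    idx <- sample.int(n_samples, n_out)
    out[idx] <- TRUE
    for (i in idx) {
      nf <- sample(1:3, 1)
      j <- sample.int(p, nf)
      x[i, j] <- x[i, j] +
        sample(c(-1, 1), nf, replace = TRUE) * stats::runif(nf, 6, 9) * sd[j]
    }
  }
  list(features = x, outlier = out)
}

#' Generate a complete synthetic cohort
#'
#' Produces every input the analysis pipeline consumes: a raw-scale
#' expression matrix with detection p-values, sample annotation (base
#' covariates + batch), a binary medication table, probe-to-gene
#' annotation, a QC-feature table with planted failures, and the ground
#' truth (planted effects, expressed flags, QC-outlier flags).
#'
#' On the log2 scale, the signal for probe g in sample i is
#' `baseline_g + sum_cov effect * covariate_i + sum_drug beta(drug, g) *
#' intake_i(drug) + location_b(g) + scale_b(g) * eps`, with
#' `eps ~ N(0, noise_sd^2)`; the emitted raw intensities are `2^signal`.
#' Detection p-values are Beta(0.5, 20) for expressed probes and
#' Uniform(0, 1) for unexpressed ones.
#'
#' The probe-level structure (gene map, expressed flags, baselines,
#' covariate- and drug-affected probe subsets and planted effect sizes)
#' is a function of `config$seed` alone, while samples, medication,
#' batch effects and noise also depend on the `cohort` index: two calls
#' with the same configuration and different `cohort` values yield
#' independent cohorts sharing the same planted truth, i.e. a
#' discovery/replication pair.
#'
#' @param config a [sim_config()].
#' @param cohort cohort index (default 1); vary it to draw an
#'   independent cohort with identical planted effects.
#' @return An object of class `sim_cohort`: a list with elements `expr`
#'   ([expression_matrix()], raw scale), `annot` (data.frame), `med`
#'   (0/1 matrix), `probe_annot` (data.frame: `probe`, `gene`,
#'   `good_mapping`), `qc` (samples x features matrix) and `truth` (list
#'   `effects` data.frame(substance, probe, beta), `expressed`,
#'   `qc_outliers`).
#' @export
generate_cohort <- function(config, cohort = 1L) {
  if (!inherits(config, "sim_config"))
    stop("generate_cohort: 'config' must be a sim_config object")
  cf <- config
  seed2 <- (cf$seed + 7919L * as.integer(cohort)) %% 2147483647L
  annot <- simulate_covariates(cf$n_samples, cf$n_batches, seed = seed2)
  med <- if (length(cf$substances))
    assign_medication(annot, cf$substances, seed = (seed2 + 1003L) %% 2147483647L,
                      control_fraction = cf$control_fraction)
  else matrix(0L, cf$n_samples, 0, dimnames = list(rownames(annot), NULL))
  qcgen <- generate_qc_features(cf$n_samples, cf$qc_outlier_fraction,
                                seed = (seed2 + 2003L) %% 2147483647L)

  set.seed(cf$seed)   # structure stream: shared across cohorts
  probes <- sprintf("P%05d", seq_len(cf$n_probes))
  # every gene gets >= 1 probe; remaining probes spread at random
  gene_of <- c(seq_len(cf$n_genes),
               sample.int(cf$n_genes, cf$n_probes - cf$n_genes, replace = TRUE))
  gene_of <- sample(gene_of)   # decouple probe order from gene index
  probe_annot <- data.frame(probe = probes,
                            gene = sprintf("G%05d", gene_of),
                            good_mapping = TRUE,
                            stringsAsFactors = FALSE)

  expressed <- stats::runif(cf$n_probes) < cf$expressed_fraction
  names(expressed) <- probes
  baseline <- ifelse(expressed, stats::rnorm(cf$n_probes, 7.5, 1.2),
                     stats::rnorm(cf$n_probes, 5.0, 0.4))

  signal <- matrix(baseline, cf$n_probes, cf$n_samples)
  dimnames(signal) <- list(probes, rownames(annot))

  # covariate effects on random probe subsets
  covs <- cbind(sex = annot$sex, age = annot$age,
                lymphocytes = annot$lymphocytes, monocytes = annot$monocytes,
                smoking = annot$smoking, log_bmi = log(annot$bmi))
  n_aff_cov <- round(cf$covariate_affected_fraction * cf$n_probes)
  for (nm in names(cf$covariate_effect_sizes)) {
    if (!nm %in% colnames(covs)) next
    eff <- cf$covariate_effect_sizes[[nm]]
    if (eff == 0 || n_aff_cov == 0) next
    aff <- sample.int(cf$n_probes, n_aff_cov)
    signal[aff, ] <- signal[aff, ] +
      eff * matrix(covs[, nm], n_aff_cov, cf$n_samples, byrow = TRUE)
  }

  # planted drug effects on expressed probes
  eff_list <- list()
  for (s in cf$substances) {
    if (s$n_affected_probes == 0) next
    pool <- which(expressed)
    if (s$n_affected_probes > length(pool))
      stop("generate_cohort: substance '", s$label,
           "' requests more affected probes than there are expressed probes")
    aff <- sample(pool, s$n_affected_probes)
    beta <- stats::runif(s$n_affected_probes,
                         s$effect_distribution[1], s$effect_distribution[2])
    if (s$down_fraction > 0) {
      flip <- stats::runif(s$n_affected_probes) < s$down_fraction
      beta[flip] <- -beta[flip]
    }
    if (any(beta != 0)) {
      keep <- beta != 0
      eff_list[[s$label]] <- data.frame(substance = s$label,
                                        probe = probes[aff][keep],
                                        beta = beta[keep],
                                        stringsAsFactors = FALSE)
      signal[aff, ] <- signal[aff, ] +
        outer(beta, as.numeric(med[, s$label]))
    }
  }
  effects <- if (length(eff_list)) do.call(rbind, c(eff_list, make.row.names = FALSE))
  else data.frame(substance = character(0), probe = character(0),
                  beta = numeric(0), stringsAsFactors = FALSE)

  # cohort stream: batch location/scale effects, residual noise,
  # detection p-values
  set.seed((seed2 + 3003L) %% 2147483647L)
  noise <- matrix(stats::rnorm(cf$n_probes * cf$n_samples, 0, cf$noise_sd),
                  cf$n_probes, cf$n_samples)
  if (cf$n_batches > 1) {
    shape <- cf$batch_scale_shape
    for (b in levels(annot$batch)) {
      in_b <- annot$batch == b
      loc <- stats::rnorm(cf$n_probes, 0, cf$batch_location_sd)
      # inverse-gamma variance multiplier with mean 1
      mult <- (shape - 1) / stats::rgamma(cf$n_probes, shape = shape, rate = 1)
      signal[, in_b] <- signal[, in_b] + loc
      noise[, in_b] <- noise[, in_b] * sqrt(mult)
    }
  }
  signal <- signal + noise

  detp <- matrix(stats::runif(cf$n_probes * cf$n_samples),
                 cf$n_probes, cf$n_samples, dimnames = dimnames(signal))
  if (any(expressed))
    detp[expressed, ] <- stats::rbeta(sum(expressed) * cf$n_samples, 0.5, 20)

  expr <- expression_matrix(2^signal, detection_p = detp, scale = "raw")
  structure(list(expr = expr, annot = annot, med = med,
                 probe_annot = probe_annot, qc = qcgen$features,
                 truth = list(effects = effects, expressed = expressed,
                              qc_outliers = qcgen$outlier)),
            class = "sim_cohort", seed = cf$seed)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d samples, %d probes, %d substances, ",
                     "%d planted effects (seed %d)\n"),
              nrow(x$annot), nrow(x$expr$values), ncol(x$med),
              nrow(x$truth$effects), attr(x, "seed")))
  invisible(x)
}
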