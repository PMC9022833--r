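# Tabular writers use 10 significant digits throughout so that
# write -> read -> write is a fixed point.
.sig10 <- function(x) if (is.numeric(x)) signif(x, 10) else x

.write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  df[] <- lapply(df, .sig10)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "", fill = FALSE)
}

.read_comments <- function(path, n = 50) {
  head_lines <- readLines(path, n = n)
  sub("^#\\s*", "", head_lines[startsWith(head_lines, "#")])
}

#' Write an expression matrix as tab-delimited text
#'
#' Probes as rows, first column `probe_id`, header row of sample ids;
#' scale tag (and, when given, the generating seed) recorded as `#`
#' comment lines. Detection p-values, when present, go to a sibling file
#' of identical shape.
#'
#' @param expr an [expression_matrix()].
#' @param path output path for intensities.
#' @param detection_path optional output path for detection p-values
#'   (defaults to none; required when `expr` carries detection p-values
#'   and you want them preserved).
#' @param seed optional integer recorded in the header comments.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, detection_path = NULL, seed = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  cm <- c(paste0("scale: ", expr$scale),
          if (!is.null(seed)) paste0("seed: ", seed))
  df <- data.frame(probe_id = rownames(expr$values),
                   .sig10(expr$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path, comments = cm)
  if (!is.null(detection_path)) {
    if (is.null(expr$detection_p))
      stop("write_expression: no detection p-values to write")
    dfp <- data.frame(probe_id = rownames(expr$detection_p),
                      .sig10(expr$detection_p), check.names = FALSE,
                      stringsAsFactors = FALSE)
    .write_tsv(dfp, detection_path, comments = cm)
  }
  invisible(path)
}

#' Read an expression matrix from tab-delimited text
#'
#' Inverse of [write_expression()]. Lines starting with `#` are skipped;
#' a `# scale:` comment sets the scale tag (default `raw`).
#'
#' @param path intensities file.
#' @param detection_path optional detection p-value file of identical
#'   shape.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, detection_path = NULL) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("read_expression: no sample columns in ", path)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("read_expression: duplicate probe id(s): ",
         paste(unique(dup), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, TRUE)
  if (any(bad))
    stop("read_expression: non-numeric cells in column(s): ",
         paste(colnames(vals)[bad], collapse = ", "))
  if (anyDuplicated(colnames(vals)))
    stop("read_expression: duplicate sample ids")
  m <- as.matrix(vals)
  rownames(m) <- ids
  cm <- .read_comments(path)
  scale <- sub("^scale:\\s*", "", grep("^scale:", cm, value = TRUE))
  if (!length(scale)) scale <- "raw"
  detp <- NULL
  if (!is.null(detection_path)) {
    dexpr <- read_expression(detection_path)
    if (!identical(dim(dexpr$values), dim(m)) ||
        !identical(dimnames(dexpr$values), dimnames(m)))
      stop("read_expression: detection p-value file shape/ids mismatch")
    detp <- dexpr$values
  }
  expression_matrix(m, detection_p = detp, scale = scale)
}

#' Write / read a binary medication table
#'
#' Rows are samples (first column `sample_id`), columns are substance
#' labels, entries 0/1.
#'
#' @param med samples x substances 0/1 matrix.
#' @param path file path.
#' @return `path` / the 0/1 integer matrix.
#' @export
write_medication <- function(med, path) {
  df <- data.frame(sample_id = rownames(med), med, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_medication
#' @export
read_medication <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!all(m %in% c(0, 1)))
    stop("read_medication: entries must be 0/1")
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m))) stop("read_medication: duplicate sample ids")
  m
}

#' Write / read a sample annotation table
#'
#' @param annot data.frame with sample ids as rownames.
#' @param path file path.
#' @return `path` / the annotation data.frame (with `batch` refactored).
#' @export
write_annotation <- function(annot, path) {
  df <- data.frame(sample_id = rownames(annot), annot, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- .read_tsv(path)
  rownames(df) <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  if ("batch" %in% colnames(df)) df$batch <- factor(df$batch)
  df
}

#' Write a sample/probe mask
#'
#' Two mandatory columns (`id`, `keep`) plus the reason code and the
#' score that triggered the decision.
#'
#' @param mask a mask data.frame as returned by the filter stages.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) .write_tsv(mask, path)

#' Pipeline configuration
#'
#' Stage toggles and thresholds for [run_discovery()] /
#' [run_replication()]. Defaults follow the analysis conventions:
#' detection at p <= 0.05 in >= 5% of samples, fences at median + 4 IQR,
#' 10% trim for the Euclidean reference, candidate prevalence > 5%,
#' >= 20 users per tested substance, 5% FDR per substance, odds-ratio
#' screen outside [0.125, 8].
#'
#' @param detection_filter,quantile_normalize,sample_qc,batch_adjust,euclidean_filter
#'   stage toggles.
#' @param alpha detection p-value cut-off.
#' @param min_fraction minimum detected-sample fraction.
#' @param k_iqr fence multiplier for both distance filters.
#' @param trim Euclidean-reference trim fraction.
#' @param min_prevalence candidate screen threshold (strict).
#' @param min_users minimum users per tested substance.
#' @param fdr FDR level (selection, discovery and replication).
#' @param or_lo,or_hi odds-ratio screen bounds.
#' @param log2_offset offset added before log2.
#' @param replication_variant hierarchical-adjustment variant (see
#'   [hierarchical_adjust()]).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(detection_filter = TRUE, quantile_normalize = TRUE,
                            sample_qc = TRUE, batch_adjust = TRUE,
                            euclidean_filter = TRUE,
                            alpha = 0.05, min_fraction = 0.05, k_iqr = 4,
                            trim = 0.10, min_prevalence = 0.05,
                            min_users = 20, fdr = 0.05,
                            or_lo = 0.125, or_hi = 8, log2_offset = 0,
                            replication_variant = "selective") {
  chk01 <- function(x, nm) if (x < 0 || x > 1)
    stop("pipeline_config: '", nm, "' must lie in [0, 1]")
  chk01(alpha, "alpha"); chk01(min_fraction, "min_fraction")
  chk01(min_prevalence, "min_prevalence"); chk01(fdr, "fdr")
  if (trim < 0 || trim >= 0.5) stop("pipeline_config: 'trim' must lie in [0, 0.5)")
  if (k_iqr <= 0) stop("pipeline_config: 'k_iqr' must be > 0")
  if (min_users < 1) stop("pipeline_config: 'min_users' must be >= 1")
  if (or_lo <= 0 || or_hi <= or_lo)
    stop("pipeline_config: need 0 < or_lo < or_hi")
  structure(list(detection_filter = detection_filter,
                 quantile_normalize = quantile_normalize,
                 sample_qc = sample_qc, batch_adjust = batch_adjust,
                 euclidean_filter = euclidean_filter,
                 alpha = alpha, min_fraction = min_fraction, k_iqr = k_iqr,
                 trim = trim, min_prevalence = min_prevalence,
                 min_users = min_users, fdr = fdr,
                 or_lo = or_lo, or_hi = or_hi, log2_offset = log2_offset,
                 replication_variant = replication_variant),
            class = "pipeline_config")
}

.manifest_row <- function(stage, din, dout, note = "") {
  data.frame(stage = stage, probes_in = din[1], samples_in = din[2],
             probes_out = dout[1], samples_out = dout[2], note = note,
             stringsAsFactors = FALSE)
}

# Shared preprocessing chain: detection filter -> quantile normalize ->
# log2 -> Mahalanobis QC -> batch adjustment (+ ANOVA check) ->
# Euclidean filter. Returns the processed pieces, the masks and the
# manifest.
.preprocess_cohort <- function(expr, annot, med, qc, config) {
  manifest <- list(); masks <- list(); anova <- NULL; batch_model <- NULL
  drop_samples <- function(keep_ids) {
    expr <<- subset_expression(expr, samples = keep_ids)
    annot <<- annot[keep_ids, , drop = FALSE]
    med <<- med[keep_ids, , drop = FALSE]
    if (!is.null(qc)) qc <<- qc[keep_ids, , drop = FALSE]
  }

  if (config$detection_filter && !is.null(expr$detection_p)) {
    din <- dim(expr)
    mask <- detection_filter(expr, config$alpha, config$min_fraction)
    expr <- subset_expression(expr, probes = mask$id[mask$keep])
    masks$detection <- mask
    manifest <- c(manifest, list(.manifest_row("detection_filter", din, dim(expr))))
  }
  if (config$quantile_normalize && expr$scale == "raw") {
    din <- dim(expr)
    expr <- quantile_normalize(expr)
    manifest <- c(manifest, list(.manifest_row("quantile_normalize", din, dim(expr))))
  }
  if (expr$scale == "raw") {
    din <- dim(expr)
    expr <- log2_transform(expr, offset = config$log2_offset)
    manifest <- c(manifest, list(.manifest_row("log2_transform", din, dim(expr))))
  }
  if (config$sample_qc && !is.null(qc)) {
    din <- dim(expr)
    mask <- mahalanobis_qc(qc, k_iqr = config$k_iqr)
    drop_samples(mask$id[mask$keep])
    masks$mahalanobis <- mask
    manifest <- c(manifest, list(.manifest_row("mahalanobis_qc", din, dim(expr))))
  }
  if (config$batch_adjust && "batch" %in% colnames(annot)) {
    din <- dim(expr)
    batch <- droplevels(factor(annot$batch))
    if (nlevels(batch) < 2) {
      manifest <- c(manifest, list(.manifest_row("batch_adjust", din, dim(expr),
                                                 "skipped: single batch")))
    } else {
      sizes <- table(batch)
      if (any(sizes < 2)) {
        # the empirical-Bayes model needs >= 2 samples per batch; drop
        # samples in singleton batches
        lone <- names(sizes)[sizes < 2]
        keep <- rownames(annot)[!batch %in% lone]
        drop_samples(keep)
        batch <- droplevels(factor(annot$batch))
      }
      cb <- combat_adjust(expr, batch,
                          covariates = base_design(annot)[, -1, drop = FALSE])
      expr <- cb$expr; batch_model <- cb$model
      anova <- batch_anova_check(expr, batch)
      manifest <- c(manifest, list(
        .manifest_row("batch_adjust", din, dim(expr),
                      sprintf("anova_frac_significant=%.4f",
                              anova$frac_significant))))
    }
  }
  if (config$euclidean_filter && ncol(expr$values) >= 10) {
    din <- dim(expr)
    mask <- euclidean_outlier_filter(expr, trim = config$trim,
                                     k_iqr = config$k_iqr)
    drop_samples(mask$id[mask$keep])
    masks$euclidean <- mask
    manifest <- c(manifest, list(.manifest_row("euclidean_filter", din, dim(expr))))
  }
  list(expr = expr, annot = annot, med = med, qc = qc, masks = masks,
       anova = anova, batch_model = batch_model,
       manifest = do.call(rbind, c(manifest, make.row.names = FALSE)))
}

#' Run the discovery analysis end to end
#'
#' Preprocessing (detection filter, quantile normalization, log2,
#' Mahalanobis QC, batch adjustment with ANOVA check, Euclidean filter),
#' polymedication adjustment-model selection, then per-substance
#' differential expression for every substance with at least
#' `config$min_users` users, with gene-level summaries.
#'
#' @param expr [expression_matrix()] (raw or log2) or a `sim_cohort`
#'   (in which case `annot`, `med`, `probe_annot` and `qc` are taken from
#'   it).
#' @param annot,med,probe_annot,qc cohort pieces (see
#'   [generate_cohort()] for the expected shapes).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, all stage outputs are
#'   written as TSV (plus a YAML manifest).
#' @return A `discovery_run`: list with `expr` (final log2 matrix),
#'   `annot`, `med`, `model`, `results` (named `de_result` list),
#'   `summary` (per-substance table: substance, n_users, n_probes,
#'   n_significant, n_up, n_down, min_q), `genes` (named list of
#'   gene-level tables), `skipped`, `background_genes`, `masks`,
#'   `anova`, `manifest`, `config`.
#' @export
run_discovery <- function(expr, annot = NULL, med = NULL, probe_annot = NULL,
                          qc = NULL, config = pipeline_config(),
                          out_dir = NULL) {
  if (inherits(expr, "sim_cohort")) {
    cohort <- expr
    expr <- cohort$expr; annot <- cohort$annot; med <- cohort$med
    probe_annot <- cohort$probe_annot; qc <- cohort$qc
  }
  stopifnot(inherits(expr, "expr_matrix"), is.data.frame(annot))
  pre <- .preprocess_cohort(expr, annot, med, qc, config)
  expr <- pre$expr; annot <- pre$annot; med <- pre$med
  manifest <- pre$manifest

  candidates <- candidate_substances(med, config$min_prevalence)
  model <- select_adjustment_substances(expr, annot, med, candidates,
                                        fdr = config$fdr)

  users <- colSums(med)
  eligible <- colnames(med)[users >= config$min_users]
  results <- list(); skipped <- character(0)
  for (lab in eligible) {
    de <- test_substance(expr, annot, med, lab, model = model,
                         min_users = config$min_users,
                         or_lo = config$or_lo, or_hi = config$or_hi,
                         probe_annot = probe_annot)
    if (is.null(de)) skipped <- c(skipped, lab) else results[[lab]] <- de
  }
  skipped <- c(skipped, setdiff(colnames(med), eligible))

  summary_tab <- do.call(rbind, c(lapply(results, summary),
                                  make.row.names = FALSE))
  genes <- NULL
  background_genes <- NULL
  if (!is.null(probe_annot)) {
    analysed <- probe_annot[probe_annot$probe %in% rownames(expr$values), ]
    background_genes <- sort(unique(analysed$gene[!is.na(analysed$gene)]))
    genes <- lapply(results, gene_level_summary, probe_annot = probe_annot,
                    q_cut = config$fdr)
  }
  run <- structure(list(expr = expr, annot = annot, med = med, model = model,
                        results = results, summary = summary_tab,
                        genes = genes, skipped = skipped,
                        background_genes = background_genes,
                        masks = pre$masks, anova = pre$anova,
                        batch_model = pre$batch_model,
                        manifest = manifest, config = config),
                   class = "discovery_run")
  if (!is.null(out_dir)) .write_discovery(run, out_dir)
  run
}

#' @export
print.discovery_run <- function(x, ...) {
  cat(sprintf("Discovery run: %d samples, %d probes analysed, %d substance(s) tested\n",
              ncol(x$expr$values), nrow(x$expr$values), length(x$results)))
  if (!is.null(x$summary) && nrow(x$summary)) {
    sig <- x$summary[x$summary$n_significant > 0, , drop = FALSE]
    cat(sprintf("  substances with >= 1 significant probe: %d\n", nrow(sig)))
    if (nrow(sig)) print(sig, row.names = FALSE)
  }
  invisible(x)
}

.write_discovery <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(run$summary))
    .write_tsv(run$summary, file.path(out_dir, "discovery_summary.tsv"))
  for (lab in names(run$results)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", lab)
    .write_tsv(as.data.frame(run$results[[lab]]),
               file.path(out_dir, paste0("de_", safe, ".tsv")))
    if (!is.null(run$genes) && !is.null(run$genes[[lab]]))
      .write_tsv(run$genes[[lab]],
                 file.path(out_dir, paste0("genes_", safe, ".tsv")))
  }
  for (nm in names(run$masks))
    write_mask(run$masks[[nm]], file.path(out_dir, paste0("mask_", nm, ".tsv")))
  .write_tsv(run$model$selection, file.path(out_dir, "adjustment_selection.tsv"))
  .write_tsv(run$model$vif, file.path(out_dir, "vif.tsv"))
  .write_tsv(run$manifest, file.path(out_dir, "manifest.tsv"))
  yaml::write_yaml(list(config = unclass(run$config),
                        timestamp = format(Sys.time(), tz = "UTC")),
                   file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Run the replication analysis end to end
#'
#' Preprocesses the replication cohort with the same configuration,
#' restricts each discovery-significant substance family to the probes
#' available on the replication platform, applies the hierarchical
#' replication procedure plus the nominal and sign-test sensitivity
#' analyses, and (when gene sets are supplied) runs per-substance
#' over-representation of replicated genes against the background of all
#' analysed genes.
#'
#' @param discovery a `discovery_run`.
#' @param expr,annot,med,probe_annot,qc the replication cohort (see
#'   [run_discovery()]).
#' @param config a [pipeline_config()] (defaults to the discovery run's).
#' @param gene_sets optional `gene_set_collection` for enrichment.
#' @param out_dir optional output directory for TSVs.
#' @return A `replication_run`: list with `replication`
#'   (`replication_result`), `sensitivity` (per-substance data.frame:
#'   n_probes, n_nominal, n_concordant, sign_test_p), `genes` (gene-level
#'   replication flags), `enrichment` (named `enrichment_result` list,
#'   deduplicated), `excluded`, `manifest`, `config`.
#' @export
run_replication <- function(discovery, expr, annot = NULL, med = NULL,
                            probe_annot = NULL, qc = NULL,
                            config = discovery$config, gene_sets = NULL,
                            out_dir = NULL) {
  stopifnot(inherits(discovery, "discovery_run"))
  if (inherits(expr, "sim_cohort")) {
    cohort <- expr
    expr <- cohort$expr; annot <- cohort$annot; med <- cohort$med
    probe_annot <- cohort$probe_annot; qc <- cohort$qc
  }
  pre <- .preprocess_cohort(expr, annot, med, qc, config)
  res <- hierarchical_replication(discovery$results, pre$expr, pre$annot,
                                  pre$med, discovery$model,
                                  discovery_q = config$fdr,
                                  q_level = config$fdr,
                                  min_users = config$min_users,
                                  variant = config$replication_variant)
  fams <- split(res$probes, res$probes$substance)
  sens_rows <- lapply(names(fams), function(lab) {
    f <- fams[[lab]]
    data.frame(substance = lab, n_probes = nrow(f),
               n_nominal = sum(f$p <= 0.05 & f$same_direction),
               n_concordant = sum(f$same_direction),
               sign_test_p = sign_test(f$direction_discovery,
                                       ifelse(f$direction_replication >= 0, 1, -1)),
               stringsAsFactors = FALSE)
  })
  sensitivity <- do.call(rbind, c(sens_rows, make.row.names = FALSE))

  genes <- NULL; enr <- NULL
  if (!is.null(probe_annot)) {
    pp <- probe_annot[, c("probe", "gene")]
    merged <- merge(res$probes, pp, by = "probe")
    agg <- stats::aggregate(replicated ~ substance + gene, data = merged, FUN = any)
    genes <- agg[order(agg$substance, agg$gene), ]
    rownames(genes) <- NULL
    if (!is.null(gene_sets)) {
      bg <- discovery$background_genes
      if (is.null(bg))
        stop("run_replication: discovery run lacks background genes; ",
             "supply probe_annot to run_discovery")
      enr <- list()
      for (lab in unique(genes$substance)) {
        hits <- genes$gene[genes$substance == lab & genes$replicated]
        hits <- intersect(hits, bg)
        if (!length(hits)) next
        e <- enrich_substance(hits, gene_sets, bg, fdr = config$fdr,
                              substance = lab)
        enr[[lab]] <- deduplicate_pathways(e)
      }
    }
  }
  run <- structure(list(replication = res, sensitivity = sensitivity,
                        genes = genes, enrichment = enr,
                        excluded = attr(res, "excluded"),
                        masks = pre$masks, manifest = pre$manifest,
                        config = config),
                   class = "replication_run")
  if (!is.null(out_dir)) .write_replication(run, out_dir)
  run
}

#' @export
print.replication_run <- function(x, ...) {
  print(x$replication)
  if (!is.null(x$excluded) && nrow(x$excluded)) {
    cat("Substances not tested in replication:\n")
    print(x$excluded, row.names = FALSE)
  }
  invisible(x)
}

.write_replication <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(run$replication$families,
             file.path(out_dir, "replication_families.tsv"))
  .write_tsv(run$replication$probes,
             file.path(out_dir, "replication_probes.tsv"))
  .write_tsv(run$sensitivity, file.path(out_dir, "replication_sensitivity.tsv"))
  if (!is.null(run$genes))
    .write_tsv(run$genes, file.path(out_dir, "replication_genes.tsv"))
  if (!is.null(run$excluded) && nrow(run$excluded))
    .write_tsv(run$excluded, file.path(out_dir, "replication_excluded.tsv"))
  if (!is.null(run$enrichment))
    for (lab in names(run$enrichment)) {
      safe <- gsub("[^A-Za-z0-9_.-]", "_", lab)
      .write_tsv(as.data.frame(run$enrichment[[lab]]),
                 file.path(out_dir, paste0("enrichment_", safe, ".tsv")))
    }
  .write_tsv(run$manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}

#' Serialize / restore a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path YAML file path.
#' @return `path` / the restored `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  lst <- unclass(config)
  lst$substances <- lapply(lst$substances, unclass)
  lst$covariate_effect_sizes <- as.list(lst$covariate_effect_sizes)
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  subs <- lapply(lst$substances, function(s)
    substance_spec(label = s$label, prevalence = s$prevalence,
                   n_affected_probes = s$n_affected_probes,
                   effect_distribution = unlist(s$effect_distribution),
                   comedication_partner = s$comedication_partner,
                   comedication_log_or = if (is.null(s$comedication_log_or)) 0
                   else s$comedication_log_or,
                   down_fraction = if (is.null(s$down_fraction)) 0.5
                   else s$down_fraction))
  sim_config(n_samples = lst$n_samples, n_probes = lst$n_probes,
             n_genes = lst$n_genes, n_batches = lst$n_batches,
             substances = subs,
             covariate_effect_sizes = unlist(lst$covariate_effect_sizes),
             covariate_affected_fraction = lst$covariate_affected_fraction,
             noise_sd = lst$noise_sd,
             batch_location_sd = lst$batch_location_sd,
             batch_scale_shape = lst$batch_scale_shape,
             qc_outlier_fraction = lst$qc_outlier_fraction,
             expressed_fraction = lst$expressed_fraction,
             control_fraction = lst$control_fraction,
             seed = lst$seed)
}
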