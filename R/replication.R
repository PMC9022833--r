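#' Hierarchical (family-wise selective) adjustment of replication tests
#'
#' Pure multiplicity step of the hierarchical replication procedure.
#' Input is one family per substance: the replication p-values of that
#' substance's discovery-significant probes, with the discovery and
#' replication effect directions. Steps: (1) BH within each family gives
#' q-values; (2) each family is summarized by its minimum q; (3) BH
#' across the family statistics at `q_level` selects families (S of M);
#' (4) within selected families, probes are declared significant at the
#' selection-adjusted level `q_level * S / M` (default variant) or at
#' `q_level` itself (`variant = "family_bh"`); (5) a probe replicates
#' when it is significant and its direction matches discovery.
#'
#' @param families named list; each element a data.frame with columns
#'   `probe`, `p`, `direction_discovery`, `direction_replication`.
#' @param q_level FDR level (default 0.05).
#' @param variant `"selective"` (selection-adjusted within-family
#'   threshold, default) or `"family_bh"` (the within-family threshold
#'   stays `q_level`; only family selection is adjusted).
#' @return A `replication_result`: list with `families` (data.frame:
#'   substance, n_probes, min_q, family_q, selected, n_replicated, n_up,
#'   n_down), `probes` (per-probe data.frame incl. `q` and `replicated`),
#'   `S`, `M`, `variant`, `q_level`.
#' @export
hierarchical_adjust <- function(families, q_level = 0.05,
                                variant = c("selective", "family_bh")) {
  variant <- match.arg(variant)
  families <- families[vapply(families, nrow, 0L) > 0]
  M <- length(families)
  if (M == 0) stop("hierarchical_adjust: no non-empty families")
  for (f in families)
    stopifnot(all(c("probe", "p", "direction_discovery",
                    "direction_replication") %in% colnames(f)))
  qs <- lapply(families, function(f) bh_adjust(f$p))
  min_q <- vapply(qs, min, 0)
  family_q <- bh_adjust(min_q)
  selected <- family_q <= q_level
  S <- sum(selected)
  thresh <- if (variant == "selective") q_level * S / max(M, 1) else q_level

  probe_rows <- vector("list", M)
  fam_rows <- vector("list", M)
  for (i in seq_len(M)) {
    f <- families[[i]]
    q <- qs[[i]]
    sig <- selected[i] & q <= thresh
    same <- f$direction_discovery == f$direction_replication &
      f$direction_replication != 0
    repl <- sig & same
    probe_rows[[i]] <- data.frame(substance = names(families)[i],
                                  probe = f$probe, p = f$p, q = q,
                                  direction_discovery = f$direction_discovery,
                                  direction_replication = f$direction_replication,
                                  same_direction = same,
                                  significant = sig, replicated = repl,
                                  stringsAsFactors = FALSE)
    fam_rows[[i]] <- data.frame(substance = names(families)[i],
                                n_probes = nrow(f), min_q = min_q[i],
                                family_q = family_q[i], selected = selected[i],
                                n_replicated = sum(repl),
                                n_up = sum(repl & f$direction_replication > 0),
                                n_down = sum(repl & f$direction_replication < 0),
                                stringsAsFactors = FALSE)
  }
  structure(list(families = do.call(rbind, c(fam_rows, make.row.names = FALSE)),
                 probes = do.call(rbind, c(probe_rows, make.row.names = FALSE)),
                 S = S, M = M, variant = variant, q_level = q_level),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf("Hierarchical replication (%s variant): %d of %d families selected at FDR %.3g\n",
              x$variant, x$S, x$M, x$q_level))
  print(x$families, row.names = FALSE)
  invisible(x)
}

#' Hierarchical replication of discovery hits in a second cohort
#'
#' For every substance with discovery-significant probes available in the
#' replication cohort, refits the association model in the replication
#' cohort (same adjustment substances, odds-ratio screen re-run on the
#' replication medication frequencies, variance moderation over the full
#' replication probe ensemble), restricts to the family's probes, and
#' applies [hierarchical_adjust()].
#'
#' @param discovery named list of discovery `de_result`s (or a
#'   `discovery_run`); families are their probes at `q <= discovery_q`.
#' @param expr,annot,med replication cohort expression (log2 scale or
#'   preprocessed matrix), annotation and medication table.
#' @param model the discovery `adjustment_model`.
#' @param discovery_q discovery significance threshold defining families
#'   (default 0.05).
#' @param q_level replication FDR level (default 0.05).
#' @param min_users minimum replication user count per substance
#'   (default 20).
#' @param variant see [hierarchical_adjust()].
#' @return A `replication_result` with an extra `excluded` attribute
#'   (data.frame of substances not tested, with reasons).
#' @export
hierarchical_replication <- function(discovery, expr, annot, med, model,
                                     discovery_q = 0.05, q_level = 0.05,
                                     min_users = 20,
                                     variant = c("selective", "family_bh")) {
  variant <- match.arg(variant)
  if (inherits(discovery, "discovery_run")) discovery <- discovery$results
  y <- .expr_values(expr)
  families <- list()
  excluded <- data.frame(substance = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  note <- function(s, r) rbind(excluded,
                               data.frame(substance = s, reason = r,
                                          stringsAsFactors = FALSE))
  for (lab in names(discovery)) {
    de <- discovery[[lab]]
    sig <- de[de$q <= discovery_q, , drop = FALSE]
    if (!nrow(sig)) next
    if (!lab %in% colnames(med)) {
      excluded <- note(lab, "not_recorded_in_replication_cohort"); next
    }
    avail <- intersect(sig$probe, rownames(y))
    if (!length(avail)) {
      excluded <- note(lab, "no_probes_on_replication_platform"); next
    }
    rde <- test_substance(y, annot, med, lab, model = model,
                          min_users = min_users)
    if (is.null(rde)) {
      excluded <- note(lab, "too_few_users_in_replication_cohort"); next
    }
    m <- match(avail, rde$probe)
    families[[lab]] <- data.frame(
      probe = avail,
      p = rde$p[m],
      direction_discovery = sig$direction[match(avail, sig$probe)],
      direction_replication = rde$direction[m],
      beta_replication = rde$beta[m],
      stringsAsFactors = FALSE)
  }
  if (!length(families))
    stop("hierarchical_replication: no substance has probes available for replication")
  res <- hierarchical_adjust(families, q_level = q_level, variant = variant)
  attr(res, "excluded") <- excluded
  res
}

#' Nominal replication flags
#'
#' The relaxed sensitivity criterion: a probe replicates nominally when
#' its replication p-value is <= `alpha` and the effect direction matches
#' discovery.
#'
#' @param families as in [hierarchical_adjust()].
#' @param alpha nominal level (default 0.05).
#' @return data.frame with `substance`, `probe`, `p`, `same_direction`,
#'   `replicated_nominal`.
#' @export
nominal_replication <- function(families, alpha = 0.05) {
  rows <- lapply(names(families), function(lab) {
    f <- families[[lab]]
    same <- f$direction_discovery == f$direction_replication &
      f$direction_replication != 0
    data.frame(substance = lab, probe = f$probe, p = f$p,
               same_direction = same,
               replicated_nominal = f$p <= alpha & same,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Exact sign test of direction concordance
#'
#' Two-sided exact binomial test of the number of concordant effect
#' directions between discovery and replication under Binomial(n, 1/2).
#'
#' @param signs_discovery,signs_replication vectors of -1/+1, equal
#'   length >= 1.
#' @return The two-sided exact p-value.
#' @export
sign_test <- function(signs_discovery, signs_replication) {
  if (length(signs_discovery) != length(signs_replication))
    stop("sign_test: sign vectors must have equal length")
  n <- length(signs_discovery)
  if (n < 1) stop("sign_test: need at least one pair")
  if (!all(abs(signs_discovery) == 1) || !all(abs(signs_replication) == 1))
    stop("sign_test: signs must be -1 or +1")
  k <- sum(signs_discovery == signs_replication)
  stats::binom.test(k, n, p = 0.5, alternative = "two.sided")$p.value
}
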