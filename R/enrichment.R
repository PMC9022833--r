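#' Read a gene-set collection from a GMT file
#'
#' Tab-delimited: set name, description, then member genes. Parsing is
#' delegated to [fgsea::gmtPathways()]; set names must be unique and sets
#' non-empty.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors (a `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets)))
    stop("read_gmt: duplicate set names in ", path)
  if (any(!vapply(sets, length, 0L)))
    stop("read_gmt: empty gene set(s) in ", path)
  structure(sets, class = "gene_set_collection")
}

#' Hypergeometric over-representation test for one gene set
#'
#' Tests whether the hit list over-represents a gene set relative to the
#' background universe of analysed genes. The set is intersected with the
#' background before testing; the p-value is the hypergeometric upper
#' tail `P(X >= k)`, and the odds ratio comes from the 2x2 table
#' `(k, n - k, K - k, N - K - n + k)` with the +0.5 correction on zero
#' cells.
#'
#' @param hits character vector of hit genes (must be a subset of
#'   `background`).
#' @param set character vector, the gene set.
#' @param background character vector, the analysed-gene universe.
#' @return `NULL` when the set is disjoint from the background;
#'   otherwise a list with `k`, `K`, `n`, `N`, `odds_ratio`, `p` and
#'   `hit_genes`.
#' @export
overrepresentation_test <- function(hits, set, background) {
  hits <- unique(hits); set <- unique(set); background <- unique(background)
  if (length(setdiff(hits, background)))
    stop("overrepresentation_test: hits must be a subset of the background")
  set <- intersect(set, background)
  if (!length(set)) return(NULL)
  N <- length(background); K <- length(set); n <- length(hits)
  hit_genes <- intersect(hits, set)
  k <- length(hit_genes)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  or <- odds_ratio_2x2(k, n - k, K - k, N - K - n + k)
  list(k = k, K = K, n = n, N = N, odds_ratio = or, p = p,
       hit_genes = sort(hit_genes))
}

#' Gene-set over-representation for one substance's replicated genes
#'
#' Tests every set in the collection against the hit list, BH-adjusts
#' across all sets jointly within the substance, and flags sets at
#' `q <= fdr`.
#'
#' @param hits character vector of replicated genes for the substance.
#' @param sets a `gene_set_collection` (named list of gene vectors).
#' @param background character vector of all analysed genes.
#' @param fdr per-substance FDR cut-off (default 0.05).
#' @param substance optional substance label carried into the result.
#' @return An `enrichment_result` data.frame: `substance`, `set`, `k`,
#'   `K`, `n`, `N`, `odds_ratio`, `p`, `q`, `significant`, `hit_genes`
#'   (comma-joined); skipped sets (disjoint from the background) are
#'   listed in the `skipped` attribute.
#' @export
enrich_substance <- function(hits, sets, background, fdr = 0.05,
                             substance = NA_character_) {
  empty <- data.frame(substance = character(0), set = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0), hit_genes = character(0),
                      stringsAsFactors = FALSE)
  hits <- unique(hits)
  if (!length(hits))
    return(structure(empty, class = c("enrichment_result", "data.frame"),
                     skipped = character(0)))
  tests <- lapply(sets, overrepresentation_test, hits = hits,
                  background = background)
  skipped <- names(sets)[vapply(tests, is.null, TRUE)]
  tests <- tests[!vapply(tests, is.null, TRUE)]
  if (!length(tests))
    return(structure(empty, class = c("enrichment_result", "data.frame"),
                     skipped = skipped))
  res <- data.frame(substance = substance, set = names(tests),
                    k = vapply(tests, `[[`, 0, "k"),
                    K = vapply(tests, `[[`, 0, "K"),
                    n = vapply(tests, `[[`, 0, "n"),
                    N = vapply(tests, `[[`, 0, "N"),
                    odds_ratio = vapply(tests, `[[`, 0, "odds_ratio"),
                    p = vapply(tests, `[[`, 0, "p"),
                    row.names = NULL, stringsAsFactors = FALSE)
  res$q <- bh_adjust(res$p)
  res$significant <- res$q <= fdr
  res$hit_genes <- vapply(tests, function(t)
    paste(t$hit_genes, collapse = ","), "")
  structure(res, class = c("enrichment_result", "data.frame"),
            skipped = skipped)
}

#' Collapse enriched pathways sharing an identical hit-gene set
#'
#' Among the significant sets, those enriched by the identical list of
#' hit genes are redundant for reporting: only the one with the highest
#' odds ratio is kept (ties: smaller p, then lexicographic set name).
#' Non-significant rows are dropped.
#'
#' @param res an `enrichment_result` from [enrich_substance()].
#' @return The deduplicated `enrichment_result`; retained hit-gene lists
#'   are pairwise distinct within each substance.
#' @export
deduplicate_pathways <- function(res) {
  stopifnot(inherits(res, "enrichment_result"))
  sig <- res[res$significant, , drop = FALSE]
  if (!nrow(sig))
    return(structure(sig, class = class(res), skipped = attr(res, "skipped")))
  key <- paste(sig$substance, sig$hit_genes, sep = "\r")
  ord <- order(key, -sig$odds_ratio, sig$p, sig$set)
  sig <- sig[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  out <- sig[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(res), skipped = attr(res, "skipped"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Over-representation: %d set(s) tested, %d significant\n",
              nrow(x), sum(x$significant)))
  if (nrow(x))
    print(utils::head(as.data.frame(x)[order(x$p),
                                       c("substance", "set", "k", "K",
                                         "odds_ratio", "p", "q")], 10),
          row.names = FALSE)
  invisible(x)
}
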