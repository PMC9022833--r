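#' Expression matrix container
#'
#' Holds a probes x samples intensity matrix together with optional
#' per-entry detection p-values and a scale tag. Intensities are stored
#' either on the raw (linear) scale, as delivered by the scanner software,
#' or on the log2 scale after [log2_transform()].
#'
#' @param values numeric matrix, probes in rows, samples in columns; both
#'   dimensions must carry unique, non-empty names (probe ids / sample ids).
#' @param detection_p optional numeric matrix of detection p-values in
#'   `[0, 1]`, conformal with `values` (same dimensions and dimnames).
#'   A small detection p-value means the probe signal is distinguishable
#'   from the negative-control background in that sample.
#' @param scale either `"raw"` or `"log2"`.
#'
#' @return An object of class `expr_matrix`: a list with elements
#'   `values`, `detection_p` and `scale`.
#' @export
expression_matrix <- function(values, detection_p = NULL, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (probes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have probe ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids in 'values'")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in 'values'")
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !all(dim(detection_p) == dim(values)))
      stop("'detection_p' must be a matrix conformal with 'values'")
    if (!identical(dimnames(detection_p), dimnames(values)))
      dimnames(detection_p) <- dimnames(values)
    rng <- range(detection_p, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop("'detection_p' entries must lie in [0, 1]")
  }
  structure(list(values = values, detection_p = detection_p, scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d probes x %d samples (%s scale)%s\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (is.null(x$detection_p)) "" else ", with detection p-values"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by probe and/or sample ids
#'
#' @param x an [expression_matrix()].
#' @param probes,samples character vectors of ids to keep (default: all).
#' @return A new `expr_matrix` restricted to the requested ids.
#' @export
subset_expression <- function(x, probes = rownames(x$values),
                              samples = colnames(x$values)) {
  stopifnot(inherits(x, "expr_matrix"))
  missing_p <- setdiff(probes, rownames(x$values))
  if (length(missing_p))
    stop("unknown probe ids: ", paste(utils::head(missing_p, 5), collapse = ", "))
  missing_s <- setdiff(samples, colnames(x$values))
  if (length(missing_s))
    stop("unknown sample ids: ", paste(utils::head(missing_s, 5), collapse = ", "))
  expression_matrix(x$values[probes, samples, drop = FALSE],
                    if (!is.null(x$detection_p))
                      x$detection_p[probes, samples, drop = FALSE],
                    scale = x$scale)
}

# Internal: coerce expr_matrix or plain matrix to a numeric matrix,
# optionally insisting on a scale tag.
.expr_values <- function(expr, require_scale = NULL) {
  if (inherits(expr, "expr_matrix")) {
    if (!is.null(require_scale) && expr$scale != require_scale)
      stop(sprintf("expression matrix must be on the %s scale (is: %s)",
                   require_scale, expr$scale))
    expr$values
  } else if (is.matrix(expr) && is.numeric(expr)) {
    expr
  } else stop("expected an 'expr_matrix' or a numeric matrix")
}
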