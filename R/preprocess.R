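#' Percentile (75th) scaling normalization across arrays
#'
#' One-color array signals are made comparable across samples by forcing a
#' chosen per-sample percentile (the 75th by default) to a common target.
#' The target is the geometric mean of the per-sample percentiles, which
#' preserves the overall intensity scale; any common target yields
#' identical downstream ratios. Percentiles use linear interpolation
#' between order statistics (R quantile type 7), fixed for bit-stability.
#'
#' @param x an `expr_matrix` (or bare positive matrix) of intensities.
#' @param percentile percentile to align, in (0, 100); default 75.
#' @return object of the same kind with each sample rescaled so that its
#'   chosen percentile equals the common target.
#' @export
percentile_normalize <- function(x, percentile = 75) {
  v <- as_values(x)
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile >= 100)
    stopf("percentile must lie strictly between 0 and 100")
  if (any(v <= 0)) stopf("percentile_normalize requires strictly positive values")
  p <- apply(v, 2L, quantile, probs = percentile / 100, names = FALSE, type = 7)
  if (any(p <= 0))
    stopf("sample '%s' has a non-positive %gth percentile",
          colnames(v)[which(p <= 0)[1L]], percentile)
  target <- exp(mean(log(p)))
  out <- sweep(v, 2L, target / p, `*`)
  rebuild(x, out)
}

#' Low-expression filtering against a pooled whole-array quantile
#'
#' The threshold is the given quantile (default 0.30) of the pooled value
#' distribution over the whole matrix (all rows and samples). A row is
#' removed iff its median across samples falls below the threshold — the
#' median is the robust per-row summary, since no per-sample rule is
#' implied by a "whole array" threshold.
#'
#' @param x an `expr_matrix` (or matrix), normally already normalized.
#' @param quantile pooled quantile defining the threshold, in (0, 1).
#' @return list with elements `matrix` (kept rows), `removed_ids` and
#'   `threshold`.
#' @export
low_expression_filter <- function(x, quantile = 0.30) {
  v <- as_values(x)
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile >= 1)
    stopf("quantile must lie strictly between 0 and 1")
  threshold <- stats::quantile(as.vector(v), probs = quantile,
                               names = FALSE, type = 7)
  med <- apply(v, 1L, median)
  drop <- med < threshold
  if (all(drop)) stopf("low_expression_filter would remove every row")
  list(matrix = rebuild(x, v[!drop, , drop = FALSE]),
       removed_ids = rownames(v)[drop],
       threshold = threshold)
}

#' Merge probes mapping to the same gene
#'
#' Per gene and sample, the merged value is the geometric mean of its
#' probes' values — consistent with the multiplicative error model, and
#' equivariant under per-sample rescaling.
#'
#' @param x an `expr_matrix` (or matrix) with probe-level rows.
#' @param probe_map data.frame with columns `probe_id`, `gene_id`; every
#'   row of `x` must be present.
#' @return object of the same kind with one row per gene. Gene order
#'   follows first appearance of each gene among the probes.
#' @export
merge_probes <- function(x, probe_map) {
  v <- as_values(x)
  validate_probe_map(probe_map)
  unmapped <- setdiff(rownames(v), probe_map$probe_id)
  if (length(unmapped))
    stopf("unmapped probe(s): %s", paste(unmapped, collapse = ", "))
  gene <- setNames(probe_map$gene_id, probe_map$probe_id)[rownames(v)]
  sums <- rowsum(log(v), gene, reorder = FALSE)
  out <- exp(sums / as.vector(table(gene)[rownames(sums)]))
  rebuild(x, out)
}

# Return a result of the same kind as the input (expr_matrix in,
# expr_matrix out; bare matrix in, bare matrix out).
rebuild <- function(x, v) {
  if (inherits(x, "expr_matrix")) expression_matrix(v, x$condition)
  else v
}
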