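#' Normalize every gene to the chosen reference genes
#'
#' Divides each sample's values by the geometric mean of the reference
#' genes' values in that sample. Any per-sample multiplicative artifact
#' `c_s` cancels exactly, because it enters numerator and reference mean
#' alike.
#'
#' @param x an `expr_matrix` (or positive matrix).
#' @param reference_genes character vector of reference gene ids; all must
#'   be present with positive values.
#' @return object of the same kind, reference-normalized.
#' @export
normalize_to_references <- function(x, reference_genes) {
  v <- as_values(x)
  missing <- setdiff(reference_genes, rownames(v))
  if (length(missing))
    stopf("reference gene(s) missing from the matrix: %s",
          paste(missing, collapse = ", "))
  refs <- v[reference_genes, , drop = FALSE]
  if (any(refs <= 0)) stopf("reference genes must have strictly positive values")
  denom <- exp(colMeans(log(refs)))
  rebuild(x, sweep(v, 2L, denom, `/`))
}

#' Per-condition relative expression (fold change) versus control
#'
#' `r(g, c)` is the ratio of the mean normalized value over condition c's
#' replicates to the mean over control replicates; the control itself has
#' r = 1 by definition. When r < 1 the percent downregulation
#' `(1 - r) * 100` is reported (NA otherwise) — e.g. r = 0.56 is a 44%
#' downregulation.
#'
#' @param x a (reference-)normalized `expr_matrix`.
#' @param design optional sample-to-condition map.
#' @param control control condition label; defaults to the first condition.
#' @return data.frame with columns `gene`, `condition`, `r`, `log2fc`,
#'   `percent_down` (long format, one row per gene x condition).
#' @export
fold_change <- function(x, design = NULL, control = NULL) {
  v <- as_values(x)
  cond <- as_condition(x, design)[colnames(v)]
  conds <- unique(cond)
  control <- control %||% conds[1L]
  if (!control %in% cond) stopf("control condition '%s' has no samples", control)
  means <- group_means(v, cond, conds)
  r <- means / means[, control]
  out <- data.frame(
    gene = rep(rownames(v), times = length(conds)),
    condition = rep(conds, each = nrow(v)),
    r = as.vector(r),
    stringsAsFactors = FALSE, row.names = NULL)
  out$log2fc <- log2(out$r)
  out$percent_down <- ifelse(out$r < 1, (1 - out$r) * 100, NA_real_)
  out
}

# genes x groups matrix of per-group row means (robust to single-row input)
group_means <- function(v, cond, conds) {
  m <- vapply(conds, function(cc)
    rowMeans(v[, cond == cc, drop = FALSE]), numeric(nrow(v)))
  matrix(m, nrow = nrow(v), dimnames = list(rownames(v), conds))
}

#' One-way ANOVA with Tukey HSD contrasts against control, per gene
#'
#' On log2 normalized values, each gene is tested with a one-way ANOVA
#' across conditions; each non-control condition is then compared with the
#' control through the Tukey HSD studentized-range test
#' (Tukey-Kramer statistic `q = |m_c - m_ctrl| / sqrt(s2/2 (1/n_c + 1/n_0))`
#' referred to `ptukey` with the full number of group means). The engine is
#' vectorized over genes; it agrees with `stats::aov` +
#' `stats::TukeyHSD` (verified in the test suite).
#'
#' With `moderate = TRUE` the per-gene residual variance is replaced by an
#' empirical-Bayes moderated variance (see [moderate_variance()]) and the
#' residual degrees of freedom are augmented by the estimated prior df, in
#' both the omnibus F-test and the Tukey contrasts.
#'
#' Degenerate rows are handled deterministically: with zero residual
#' variance, a zero between-group spread gives p = 1 and any non-zero
#' spread gives p = 0.
#'
#' @param x a normalized `expr_matrix` of strictly positive values.
#' @param design optional sample-to-condition map.
#' @param control control condition label; defaults to the first condition.
#' @param moderate logical; apply empirical-Bayes variance moderation.
#' @return data.frame with one row per gene x non-control condition:
#'   `gene`, `condition`, `p` (Tukey HSD), `omnibus_p` (ANOVA F-test).
#'   Attributes `s2` (residual variances used) and `df` (residual df).
#' @export
anova_tukey <- function(x, design = NULL, control = NULL, moderate = FALSE) {
  v <- as_values(x)
  cond <- as_condition(x, design)[colnames(v)]
  conds <- unique(cond)
  control <- control %||% conds[1L]
  if (!control %in% conds) stopf("control condition '%s' has no samples", control)
  n_i <- table(cond)[conds]
  if (any(n_i < 2L))
    stopf("condition '%s' has fewer than 2 replicates",
          names(n_i)[n_i < 2L][1L])
  k <- length(conds)
  if (k < 2L) stopf("need at least two conditions")
  N <- ncol(v)
  df <- N - k
  lg <- log2(v)

  m <- group_means(lg, cond, conds)
  ssw <- rowSums((lg - m[, cond, drop = FALSE])^2)
  grand <- as.vector(m %*% as.vector(n_i)) / N
  ssb <- as.vector((m - grand)^2 %*% as.vector(n_i))
  s2 <- ssw / df
  df_eff <- rep(df, nrow(v))
  if (moderate) {
    mod <- moderate_variance(s2, df)
    s2 <- mod$var_post
    df_eff <- rep(df + mod$prior_df, nrow(v))
    if (!all(is.finite(df_eff))) df_eff <- rep(Inf, nrow(v))
  }

  tol <- 1e-10 * pmax(rowMeans(lg^2), 1)
  zerovar <- s2 <= tol
  f <- (ssb / (k - 1L)) / s2
  omnibus <- ifelse(zerovar, ifelse(ssb <= tol, 1, 0),
                    pf(f, k - 1L, df_eff, lower.tail = FALSE))

  out <- do.call(rbind, lapply(setdiff(conds, control), function(cc) {
    diff <- abs(m[, cc] - m[, control])
    se <- sqrt(s2 / 2 * (1 / n_i[[cc]] + 1 / n_i[[control]]))
    p <- ifelse(zerovar, ifelse(diff <= sqrt(tol), 1, 0),
                ptukey(diff / se, nmeans = k, df = df_eff, lower.tail = FALSE))
    data.frame(gene = rownames(v), condition = cc, p = unname(p),
               omnibus_p = unname(omnibus),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  attr(out, "s2") <- s2
  attr(out, "df") <- df_eff[1L]
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values with monotonicity enforcement, as implemented
#' by `stats::p.adjust(method = "BH")`; input order is preserved.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues)) stopf("pvalues must be numeric")
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) stopf("p-value outside [0, 1] at position %d", which(!ok)[1L])
  p.adjust(pvalues, method = "BH")
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Shrinks each gene's residual variance towards a common prior:
#' `s2_tilde = (d0 * s0^2 + df * s2) / (d0 + df)`. When the prior
#' `(d0, s0^2)` is not supplied it is estimated from the ensemble of
#' variances by moment matching on the log scale under the scaled-F model
#' (via `limma::fitFDist`). `d0 = 0` returns the variances unchanged;
#' `d0 = Inf` returns `s0^2` for every gene.
#'
#' @param s2 numeric vector of per-gene residual variances (>= 0).
#' @param df residual degrees of freedom (scalar or vector, >= 1).
#' @param prior_df prior degrees of freedom d0 (>= 0); estimated if NULL.
#' @param prior_var prior variance s0^2; estimated if NULL.
#' @return list with `var_post` (moderated variances), `prior_df`,
#'   `prior_var`.
#' @export
moderate_variance <- function(s2, df, prior_df = NULL, prior_var = NULL) {
  if (any(!is.na(s2) & s2 < 0)) stopf("variances must be non-negative")
  if (any(df < 1)) stopf("df must be >= 1")
  if (is.null(prior_df) || is.null(prior_var)) {
    fit <- limma::fitFDist(s2, df1 = df)
    prior_df <- prior_df %||% fit$df2
    prior_var <- prior_var %||% fit$scale
  }
  if (any(prior_df < 0)) stopf("prior_df must be >= 0")
  if (any(prior_df + df == 0)) stopf("prior_df + df must be positive")
  var_post <- if (any(!is.finite(prior_df))) rep(prior_var, length(s2))
  else (prior_df * prior_var + df * s2) / (prior_df + df)
  list(var_post = var_post, prior_df = prior_df, prior_var = prior_var)
}

#' Call differential expression with fold-change, p and FDR cutoffs
#'
#' A gene x condition cell is called `down` iff `r <= 1/fc_cutoff`,
#' `p < p_cutoff` and `q < fdr_cutoff`; `up` iff `r >= fc_cutoff` with the
#' same statistical thresholds; otherwise `none`. The fold-change boundary
#' is inclusive. When `stats` lacks a `q` column, q-values are computed by
#' [bh_fdr()] over all supplied contrast p-values.
#'
#' @param fc fold-change table from [fold_change()].
#' @param stats per-contrast statistics from [anova_tukey()] (columns
#'   `gene`, `condition`, `p`, optionally `q`).
#' @param fc_cutoff absolute fold-change cutoff (default 2).
#' @param p_cutoff p-value cutoff (default 0.01).
#' @param fdr_cutoff FDR cutoff (default 0.1).
#' @return data.frame with columns `gene`, `condition`, `r`, `p`, `q`,
#'   `call` for every gene x condition present in `stats`.
#' @export
call_de <- function(fc, stats, fc_cutoff = 2, p_cutoff = 0.01,
                    fdr_cutoff = 0.1) {
  need_fc <- c("gene", "condition", "r")
  need_st <- c("gene", "condition", "p")
  if (!all(need_fc %in% names(fc))) stopf("fc lacks columns gene/condition/r")
  if (!all(need_st %in% names(stats))) stopf("stats lacks columns gene/condition/p")
  if (fc_cutoff <= 1) stopf("fc_cutoff must be > 1")
  key_fc <- paste(fc$gene, fc$condition, sep = "\r")
  key_st <- paste(stats$gene, stats$condition, sep = "\r")
  if (anyDuplicated(key_st)) stopf("stats has duplicated gene x condition rows")
  miss <- setdiff(key_st, key_fc)
  if (length(miss))
    stopf("tables misaligned: %d gene x condition cell(s) missing from fc",
          length(miss))
  q <- if ("q" %in% names(stats)) stats$q else bh_fdr(stats$p)
  r <- fc$r[match(key_st, key_fc)]
  p <- stats$p
  pass <- !is.na(p) & !is.na(q) & p < p_cutoff & q < fdr_cutoff
  call <- rep("none", nrow(stats))
  call[pass & r <= 1 / fc_cutoff] <- "down"
  call[pass & r >= fc_cutoff] <- "up"
  data.frame(gene = stats$gene, condition = stats$condition,
             r = r, p = p, q = q, call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}
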