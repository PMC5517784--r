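#' geNorm expression-stability measure M
#'
#' For every pair of candidate reference genes j, k the pairwise variation
#' `V_jk` is the sample standard deviation (n - 1 denominator) over samples
#' of `log2(x_j / x_k)`. The stability measure of gene j is
#' `M_j = mean over k != j of V_jk`; lower M means more stable. M is
#' invariant to per-sample scaling because within-sample ratios cancel any
#' common factor.
#'
#' @param x an `expr_matrix` or positive matrix restricted to the candidate
#'   genes (rows).
#' @return named numeric vector of M values (one per candidate).
#' @examples
#' m <- rbind(g1 = c(1, 2, 4), g2 = c(2, 4, 8), g3 = c(1, 1, 1))
#' colnames(m) <- paste0("s", 1:3)
#' genorm_m_values(m)  # g1 0.5, g2 0.5, g3 1.0
#' @export
genorm_m_values <- function(x) {
  v <- as_values(x)
  if (nrow(v) < 2L) stopf("geNorm needs at least 2 candidate genes")
  if (ncol(v) < 2L) stopf("geNorm needs at least 2 samples")
  if (any(v <= 0)) stopf("geNorm requires strictly positive values")
  lg <- log2(v)
  n <- nrow(lg)
  V <- matrix(0, n, n, dimnames = list(rownames(lg), rownames(lg)))
  for (j in seq_len(n - 1L))
    for (k in (j + 1L):n)
      V[j, k] <- V[k, j] <- sd(lg[j, ] - lg[k, ])
  setNames(rowSums(V) / (n - 1L), rownames(lg))
}

#' geNorm stepwise ranking of candidate reference genes
#'
#' Iteratively recomputes M on the surviving candidate set and excludes the
#' gene with the largest M, until two genes remain; the final pair cannot
#' be separated by the pairwise measure and shares rank 1. Ties in the
#' exclusion step are broken by removing the lexicographically greatest
#' gene id, so an all-proportional candidate set yields a purely
#' lexicographic ranking.
#'
#' @param x candidate-gene `expr_matrix` or positive matrix (>= 3 genes).
#' @return list with `table` (data.frame: gene, M at exclusion — or in the
#'   final pair —, rank) and `exclusion_order` (least stable first).
#' @export
genorm_rank <- function(x) {
  v <- as_values(x)
  if (nrow(v) < 3L) stopf("geNorm ranking needs at least 3 candidates")
  excluded <- character(0)
  m_at <- numeric(0)
  surviving <- v
  while (nrow(surviving) > 2L) {
    M <- genorm_m_values(surviving)
    worst <- max(M)
    drop_id <- max(names(M)[M == worst])  # lexicographic tie-break
    excluded <- c(excluded, drop_id)
    m_at <- c(m_at, M[[drop_id]])
    surviving <- surviving[rownames(surviving) != drop_id, , drop = FALSE]
  }
  final_m <- genorm_m_values(surviving)
  final_pair <- sort(names(final_m))
  tab <- data.frame(
    gene = c(final_pair, rev(excluded)),
    M = c(final_m[final_pair], rev(m_at)),
    rank = c(1L, 1L, seq_len(length(excluded)) + 1L),
    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab, exclusion_order = excluded)
}

#' NormFinder model-based stability value
#'
#' Implements the model-based variance decomposition of Andersen et al.'s
#' NormFinder on log2 data. Sample effects are removed by centring each
#' sample over the candidate genes; per gene and group this yields an
#' intragroup variance estimate (with the k/(k-2) bias correction that
#' accounts for the centring, k = number of candidates) and an intergroup
#' deviation d (the gene's group mean corrected by the group's average
#' deviation over all candidates). The intergroup deviations are shrunk
#' towards zero by their estimated signal-to-noise ratio, and the
#' stability value of a gene is the average over groups of
#' |shrunken d| + its posterior standard error. Lower = more stable.
#'
#' @param x candidate-gene `expr_matrix` or positive matrix (>= 3 genes).
#' @param design optional sample-to-condition map (vector named by sample
#'   or data.frame with columns `sample`, `condition`); taken from `x`
#'   when it is an `expr_matrix`.
#' @return named numeric vector of stability values.
#' @export
normfinder_stability <- function(x, design = NULL) {
  v <- as_values(x)
  group <- as_condition(x, design)[colnames(v)]
  if (anyNA(group)) stopf("every sample needs a condition")
  k <- nrow(v)
  if (k < 3L) stopf("NormFinder needs at least 3 candidate genes")
  tabg <- table(group)
  if (length(tabg) < 2L) stopf("NormFinder needs at least 2 groups")
  if (any(tabg < 2L))
    stopf("group '%s' has fewer than 2 samples", names(tabg)[tabg < 2L][1L])
  if (any(v <= 0)) stopf("NormFinder requires strictly positive values")

  ly <- log2(v)
  z <- sweep(ly, 2L, colMeans(ly))          # remove sample effects
  groups <- names(tabg)
  G <- length(groups)
  zbar <- sapply(groups, function(g) rowMeans(z[, group == g, drop = FALSE]))
  s2 <- sapply(groups, function(g) apply(z[, group == g, drop = FALSE], 1L, var))
  n_g <- as.vector(tabg[groups])

  # unbiased intragroup variances: centring over k genes deflates each
  # gene's variance and mixes in the others', inverted by
  # sigma2 = (s2 - S/(k(k-1))) * k/(k-2), S = column sum of s2
  S <- colSums(s2)
  sigma2 <- pmax(sweep(s2, 2L, S / (k * (k - 1L))) * k / (k - 2L), 0)
  vd <- sweep(sigma2, 2L, n_g, `/`)         # sampling variance of each d

  d <- zbar - rowMeans(zbar)                # intergroup deviations
  gamma2 <- pmax(rowSums(d^2) / (G - 1L) - rowMeans(vd), 0)

  shrink <- sweep(vd, 1L, gamma2,
                  function(v, g2) ifelse(g2 + v > 0, g2 / (g2 + v), 0))
  dstar <- d * shrink
  post_var <- vd * shrink
  setNames(rowMeans(abs(dstar) + sqrt(post_var)), rownames(v))
}

#' One-way ANOVA screen for condition-dependent candidates
#'
#' Per candidate gene, a one-way ANOVA F-test on log2 values across the
#' condition groups (`stats::oneway.test` with equal variances, i.e. the
#' classical fixed-effects ANOVA). Genes with p < alpha are flagged as
#' significantly variable and therefore unsuitable references.
#'
#' @param x candidate-gene `expr_matrix` or positive matrix.
#' @param design optional sample-to-condition map (see
#'   [normfinder_stability()]).
#' @param alpha significance level for the `variable` flag (default 0.05).
#' @return data.frame with columns `gene`, `p`, `variable`.
#' @export
anova_screen <- function(x, design = NULL, alpha = 0.05) {
  v <- as_values(x)
  group <- factor(as_condition(x, design)[colnames(v)])
  if (nlevels(group) < 2L) stopf("ANOVA screen needs at least 2 groups")
  if (any(table(group) < 2L)) stopf("every group needs at least 2 samples")
  if (any(v <= 0)) stopf("anova_screen requires strictly positive values")
  lg <- log2(v)
  p <- apply(lg, 1L, function(y) {
    if (var(y) == 0) return(1)  # flat gene: nothing to test
    oneway.test(y ~ group, var.equal = TRUE)$p.value
  })
  data.frame(gene = rownames(v), p = unname(p), variable = unname(p) < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Combined reference-gene stability table
#'
#' Runs the geNorm stepwise ranking, NormFinder and the ANOVA screen on a
#' candidate panel and assembles one table. Ranks are dense (tied values
#' share a rank); NormFinder ties are broken for display order — not rank —
#' lexicographically.
#'
#' @param x an `expr_matrix` covering at least the candidate genes.
#' @param candidates character vector of candidate gene ids (>= 3).
#' @param design optional sample-to-condition map.
#' @return data.frame with columns `gene`, `genorm_M`, `genorm_rank`,
#'   `normfinder_value`, `normfinder_rank`, `anova_p`, `variable`, ordered
#'   by geNorm rank.
#' @export
stability_table <- function(x, candidates, design = NULL) {
  v <- as_values(x)
  missing <- setdiff(candidates, rownames(v))
  if (length(missing))
    stopf("candidate gene(s) absent from the matrix: %s",
          paste(missing, collapse = ", "))
  sub <- v[candidates, , drop = FALSE]
  cond <- as_condition(x, design)
  gr <- genorm_rank(sub)
  nf <- normfinder_stability(sub, cond)
  av <- anova_screen(sub, cond)
  tab <- gr$table
  names(tab) <- c("gene", "genorm_M", "genorm_rank")
  tab$normfinder_value <- nf[tab$gene]
  tab$normfinder_rank <- dense_rank(round(nf, 12))[match(tab$gene, names(nf))]
  tab$anova_p <- av$p[match(tab$gene, av$gene)]
  tab$variable <- av$variable[match(tab$gene, av$gene)]
  rownames(tab) <- NULL
  tab
}
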