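# Fixtures and independent brute-force oracles used across the suite.

# small three-condition scenario: 2 stable refs, 1 shifted gene, 1 noisy-only
# gene, a handful of filler rows
small_config <- function(noise_sd_log2 = 0.1, seed = 42L,
                         probe_multiplicity = 1L, reps = 4L) {
  genes <- c(
    list(gene_spec("ref1", "reference_stable"),
         gene_spec("ref2", "reference_stable"),
         gene_spec("hit", "pathway_member", pathway = "pw",
                   effects = c(A = 0.5, B = 0.25)),
         gene_spec("flat", "pathway_member", pathway = "pw")),
    lapply(sprintf("bg%02d", 1:6), gene_spec, role = "filler"))
  simulation_config(conditions = c("ctrl", "A", "B"), genes = genes,
                    replicates_per_condition = reps,
                    noise_sd_log2 = noise_sd_log2,
                    probe_multiplicity = probe_multiplicity, seed = seed)
}

random_matrix <- function(nr, nc, seed, prefix = "g") {
  set.seed(seed)
  m <- matrix(2^rnorm(nr * nc, 10, 1), nr, nc,
              dimnames = list(paste0(prefix, seq_len(nr)),
                              paste0("s", seq_len(nc))))
  m
}

# brute-force geNorm M: literal double loop over gene pairs
oracle_genorm_m <- function(m) {
  lg <- log2(m)
  n <- nrow(lg)
  M <- numeric(n)
  for (j in seq_len(n)) {
    vs <- c()
    for (k in seq_len(n)) {
      if (k == j) next
      vs <- c(vs, sd(lg[j, ] - lg[k, ]))
    }
    M[j] <- mean(vs)
  }
  setNames(M, rownames(m))
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  adj <- p[o] * n / seq_len(n)
  for (i in seq_len(n)) adj[i] <- min(adj[i:n], 1)
  q[o] <- adj
  q
}

# brute-force NormFinder following the model-based decomposition with
# explicit loops (independent of the vectorized implementation)
oracle_normfinder <- function(m, group) {
  ly <- log2(m)
  k <- nrow(ly)
  groups <- unique(group)
  G <- length(groups)
  z <- ly
  for (s in seq_len(ncol(ly))) z[, s] <- ly[, s] - mean(ly[, s])
  zbar <- s2 <- matrix(0, k, G, dimnames = list(rownames(m), groups))
  n_g <- integer(G)
  for (gi in seq_along(groups)) {
    idx <- which(group == groups[gi])
    n_g[gi] <- length(idx)
    for (i in seq_len(k)) {
      zbar[i, gi] <- mean(z[i, idx])
      s2[i, gi] <- var(z[i, idx])
    }
  }
  sigma2 <- s2
  for (gi in seq_len(G)) {
    S <- sum(s2[, gi])
    for (i in seq_len(k))
      sigma2[i, gi] <- max((s2[i, gi] - S / (k * (k - 1))) * k / (k - 2), 0)
  }
  rho <- numeric(k)
  for (i in seq_len(k)) {
    d <- zbar[i, ] - mean(zbar[i, ])
    vd <- sigma2[i, ] / n_g
    g2 <- max(sum(d^2) / (G - 1) - mean(vd), 0)
    acc <- 0
    for (gi in seq_len(G)) {
      w <- if (g2 + vd[gi] > 0) g2 / (g2 + vd[gi]) else 0
      acc <- acc + abs(d[gi] * w) + sqrt(vd[gi] * w)
    }
    rho[i] <- acc / G
  }
  setNames(rho, rownames(m))
}

# stability-stage shortcut used by recovery studies: percentile-normalize,
# merge probes, rank the candidate panel
scenario_stability <- function(cfg, seed) {
  x <- generate_expression(cfg, seed_override = seed)
  pre <- percentile_normalize(x)
  merged <- if (cfg$probe_multiplicity > 1L)
    merge_probes(pre, scenario_probe_map(cfg)) else pre
  stability_table(merged, scenario_candidates(cfg))
}

stable_refs <- c("Mrpl19", "Hprt", "B2m", "Tfrc")
unstable_refs <- c("ActB", "Gapdh")
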