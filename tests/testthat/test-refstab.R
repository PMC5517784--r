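test_that("geNorm M reproduces the hand-computed worked example", {
  m <- rbind(g1 = c(1, 2, 4), g2 = c(2, 4, 8), g3 = c(1, 1, 1))
  colnames(m) <- paste0("s", 1:3)
  # V(g1,g2) = 0 (constant ratio), V(g1,g3) = V(g2,g3) = sd(c(0,1,2)) = 1
  expect_equal(genorm_m_values(m), c(g1 = 0.5, g2 = 0.5, g3 = 1.0))

  # perfectly proportional pair: M = 0 for both
  prop <- rbind(a = c(1, 3, 5), b = c(2, 6, 10))
  colnames(prop) <- paste0("s", 1:3)
  expect_equal(genorm_m_values(prop), c(a = 0, b = 0))

  # per-sample scaling cancels in within-sample ratios
  m10 <- m; m10[, 2] <- m10[, 2] * 10
  expect_equal(genorm_m_values(m10), genorm_m_values(m))

  expect_error(genorm_m_values(m[1, , drop = FALSE]), "2 candidate")
  expect_error(genorm_m_values(m[, 1, drop = FALSE]), "2 samples")
})

test_that("geNorm M equals the brute-force pairwise oracle on random panels", {
  for (seed in 1:10) {
    m <- random_matrix(5, 6, seed = 100 + seed)
    expect_equal(genorm_m_values(m), oracle_genorm_m(m), tolerance = 1e-12)
  }
})

test_that("geNorm stepwise ranking excludes least stable first, ties at rank 1", {
  m <- rbind(g1 = c(1, 2, 4), g2 = c(2, 4, 8), g3 = c(1, 1, 1))
  colnames(m) <- paste0("s", 1:3)
  r <- genorm_rank(m)
  expect_identical(r$exclusion_order, "g3")
  expect_equal(r$table$gene, c("g1", "g2", "g3"))
  expect_equal(r$table$rank, c(1L, 1L, 2L))

  # all pairwise proportional: all M = 0, ranking purely lexicographic
  base <- c(1, 3, 7, 9)
  prop <- rbind(d = 4 * base, b = 2 * base, a = base, c = 3 * base)
  colnames(prop) <- paste0("s", 1:4)
  r2 <- genorm_rank(prop)
  expect_equal(r2$table$gene, c("a", "b", "c", "d"))
  expect_equal(r2$table$rank, c(1L, 1L, 2L, 3L))
})

test_that("NormFinder matches the brute-force model-based oracle", {
  group <- rep(c("x", "y"), each = 4)
  for (seed in 1:8) {
    m <- random_matrix(4, 8, seed = 200 + seed)
    expect_equal(normfinder_stability(m, setNames(group, colnames(m))),
                 oracle_normfinder(m, group), tolerance = 1e-12)
  }
})

test_that("NormFinder penalizes group shifts above equal-variance noise", {
  # 2 groups x 4 samples; 'shifted' carries its variance as an intergroup
  # jump, 'noisy' carries the same total variance as i.i.d. noise
  set.seed(11)
  group <- rep(c("x", "y"), each = 4)
  shift <- 0.8
  build <- function() {
    lg <- rbind(
      shifted = c(rnorm(4, 0, 0.05), rnorm(4, shift, 0.05)),
      noisy = rnorm(8, 0, sqrt(0.05^2 + shift^2 / 4)),
      r1 = rnorm(8, 5, 0.05), r2 = rnorm(8, 7, 0.05), r3 = rnorm(8, 9, 0.05))
    colnames(lg) <- paste0("s", 1:8)
    2^lg
  }
  worse <- vapply(1:50, function(i) {
    s <- normfinder_stability(build(), setNames(group, paste0("s", 1:8)))
    s["shifted"] > s["noisy"]
  }, logical(1))
  expect_gte(mean(worse), 0.9)

  # all candidates constant: all stability values are exactly zero
  flat <- matrix(2^5, 3, 8, dimnames = list(c("a", "b", "c"), paste0("s", 1:8)))
  expect_equal(normfinder_stability(flat, setNames(group, colnames(flat))),
               c(a = 0, b = 0, c = 0))

  # adding a constant to all log-values of one sample (a sample effect)
  # leaves the values untouched
  m <- random_matrix(4, 8, seed = 300)
  m2 <- m; m2[, 3] <- m2[, 3] * 2^1.7
  gr <- setNames(group, colnames(m))
  expect_equal(normfinder_stability(m2, gr), normfinder_stability(m, gr),
               tolerance = 1e-10)

  expect_error(normfinder_stability(m[1:2, ], gr), "3 candidate")
  expect_error(
    normfinder_stability(m, setNames(c("x", rep("y", 7)), colnames(m))),
    "fewer than 2 samples")
})

test_that("ANOVA screen reproduces the hand ANOVA and calibrates its size", {
  # log2 groups (1,2,3) vs (2,3,4): F = 1.5 on (1,4) df, p = 0.2879
  m <- matrix(2^c(1, 2, 3, 2, 3, 4), nrow = 1,
              dimnames = list("g", paste0("s", 1:6)))
  res <- anova_screen(m, setNames(rep(c("x", "y"), each = 3), colnames(m)))
  expect_equal(res$p, 0.2879, tolerance = 1e-3)
  expect_false(res$variable)

  # type-I error under the null ~ alpha (vectorized over many null genes)
  set.seed(21)
  n <- 2000
  null_m <- matrix(2^rnorm(n * 8, 8, 0.5), n, 8,
                   dimnames = list(paste0("g", 1:n), paste0("s", 1:8)))
  gr <- setNames(rep(c("x", "y"), each = 4), colnames(null_m))
  rate <- mean(anova_screen(null_m, gr)$p < 0.05)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(rate - 0.05), 2.5 * se)
})

test_that("the screen detects a 2-fold shift at typical array noise", {
  # delta = 0.5 in one of two conditions, noise_sd_log2 = 0.1, n = 4
  hits <- vapply(1:500, function(i) {
    set.seed(4000 + i)
    y <- 2^c(rnorm(4, 10, 0.1), rnorm(4, 9, 0.1))
    m <- matrix(y, 1, dimnames = list("g", paste0("s", 1:8)))
    anova_screen(m, setNames(rep(c("c", "t"), each = 4), colnames(m)))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("stability table integrates both rankings on the default scenario", {
  st <- scenario_stability(default_scenario(), seed = 5L)
  expect_setequal(st$gene, c(stable_refs, unstable_refs))
  # the four simulated-stable references outrank the unstable candidates
  expect_lt(max(st$genorm_rank[match(stable_refs, st$gene)]),
            min(st$genorm_rank[match(unstable_refs, st$gene)]))
  nf <- setNames(st$normfinder_value, st$gene)
  expect_lt(max(nf[stable_refs]), min(nf[unstable_refs]))
  # unstable housekeeping genes are flagged by the ANOVA screen
  expect_true(all(st$variable[match(unstable_refs, st$gene)]))
  expect_error(stability_table(random_matrix(3, 4, 1), c("g1", "zz")),
               "absent.*zz")
})
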