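test_that("reference normalization cancels per-sample artifacts exactly", {
  m <- random_matrix(6, 5, seed = 31)
  refs <- c("g1", "g2")
  artifact <- c(1, 10, 0.2, 3, 7)
  a <- normalize_to_references(sweep(m, 2, artifact, `*`), refs)
  b <- normalize_to_references(m, refs)
  expect_equal(a, b, tolerance = 1e-12)

  # a single constant reference changes values only by a global constant
  m2 <- m; m2["g1", ] <- 50
  n2 <- normalize_to_references(m2, "g1")
  expect_equal(n2, m2 / 50, tolerance = 1e-12)

  expect_error(normalize_to_references(m, c("g1", "nope")), "nope")
})

test_that("fold change recovers configured effects and percent-down", {
  cfg <- small_config(noise_sd_log2 = 0)
  x <- generate_expression(cfg)
  fc <- fold_change(normalize_to_references(x, c("ref1", "ref2")))
  hitA <- fc[fc$gene == "hit" & fc$condition == "A", ]
  expect_equal(hitA$r, 0.5, tolerance = 1e-12)
  expect_equal(hitA$log2fc, -1, tolerance = 1e-12)
  expect_equal(hitA$percent_down, 50, tolerance = 1e-12)
  # r = 0.56 corresponds to a 44% downregulation
  expect_equal((1 - 0.56) * 100, 44)
  # control column is identically 1, percent_down undefined at r >= 1
  ctrl <- fc[fc$condition == "ctrl", ]
  expect_true(all(ctrl$r == 1))
  expect_true(all(is.na(ctrl$percent_down)))
  flatA <- fc[fc$gene == "flat" & fc$condition == "A", ]
  expect_equal(flatA$r, 1, tolerance = 1e-12)
})

test_that("vectorized ANOVA/Tukey agrees with stats::aov + stats::TukeyHSD", {
  set.seed(55)
  k <- 4; reps <- 3
  conds <- c("ctrl", paste0("t", 1:(k - 1)))
  cond <- setNames(rep(conds, each = reps),
                   paste0(rep(conds, each = reps), "_", seq_len(reps)))
  m <- matrix(2^rnorm(12 * length(cond), 8, 0.7), 12, length(cond),
              dimnames = list(paste0("g", 1:12), names(cond)))
  got <- anova_tukey(m, design = cond)
  for (g in rownames(m)) {
    y <- log2(m[g, ])
    f <- factor(cond, levels = conds)
    fit <- aov(y ~ f)
    p_omni <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$f
    for (cc in conds[-1]) {
      row <- got[got$gene == g & got$condition == cc, ]
      expect_equal(row$omnibus_p, p_omni, tolerance = 1e-9)
      pair <- grep(sprintf("(^%s-ctrl$|^ctrl-%s$)", cc, cc), rownames(tk))
      expect_equal(row$p, unname(tk[pair, "p adj"]), tolerance = 1e-9)
    }
  }
})

test_that("ANOVA/Tukey handles degenerate and two-group cases", {
  # identical data in every condition: p-values indistinguishable from 1
  flat <- matrix(32, 2, 6, dimnames = list(c("a", "b"), paste0("s", 1:6)))
  cond <- setNames(rep(c("ctrl", "x", "y"), each = 2), colnames(flat))
  got <- anova_tukey(flat, design = cond)
  expect_true(all(got$p >= 0.99))
  expect_true(all(got$omnibus_p >= 0.99))

  # two groups: Tukey HSD reduces to the two-sided pooled-variance t-test
  set.seed(9)
  m <- matrix(2^rnorm(8 * 5, 8, 0.4), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  cond2 <- setNames(rep(c("ctrl", "trt"), each = 4), colnames(m))
  got2 <- anova_tukey(m, design = cond2)
  for (g in rownames(m)) {
    tt <- t.test(log2(m[g, 5:8]), log2(m[g, 1:4]), var.equal = TRUE)$p.value
    # identity is analytic; ptukey itself is accurate to ~1e-8
    expect_equal(got2$p[got2$gene == g], tt, tolerance = 1e-6)
  }

  expect_error(anova_tukey(m, design = setNames(c("a", rep("b", 7)),
                                                colnames(m))),
               "fewer than 2 replicates")
})

test_that("Tukey contrast detects a configured 2-fold effect reliably", {
  # delta = 0.5, noise_sd_log2 = 0.1, n = 4/group, 6 groups
  hits <- vapply(1:300, function(i) {
    set.seed(7000 + i)
    lg <- c(rnorm(4, 10, 0.1), rnorm(4, 9, 0.1), rnorm(16, 10, 0.1))
    m <- matrix(2^lg, 1, dimnames = list("g", paste0("s", 1:24)))
    cond <- setNames(rep(c("ctrl", "hit", "c3", "c4", "c5", "c6"), each = 4),
                     colnames(m))
    st <- anova_tukey(m, design = cond)
    st$p[st$condition == "hit"] < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  for (seed in 1:10) {
    set.seed(600 + seed)
    p <- runif(sample(3:20, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.1, 1.4)), "outside")
})

test_that("variance moderation shrinks towards the prior as specified", {
  expect_equal(moderate_variance(3, df = 4, prior_df = 4, prior_var = 1)$var_post, 2)
  expect_equal(moderate_variance(c(1, 3, 9), df = 5, prior_df = 0,
                                 prior_var = 7)$var_post, c(1, 3, 9))
  expect_equal(moderate_variance(c(1, 3), df = 5, prior_df = Inf,
                                 prior_var = 2)$var_post, c(2, 2))
  # moment-matched prior pulls an outlying variance towards the ensemble
  set.seed(77)
  s2 <- c(rchisq(50, 4) / 4, 40)
  mod <- moderate_variance(s2, df = 4)
  expect_gt(mod$prior_df, 0)
  expect_lt(mod$var_post[51], 40)
  expect_gt(mod$var_post[51], mean(s2[1:50]))
  expect_error(moderate_variance(-1, df = 4), "non-negative")
})

test_that("DE calls enforce all three thresholds with inclusive boundaries", {
  fc <- data.frame(gene = paste0("g", 1:6), condition = "t",
                   r = c(0.4, 0.4, 0.5, 3.0, 0.9, 0.51))
  st <- data.frame(gene = paste0("g", 1:6), condition = "t",
                   p = c(0.001, 0.001, 0.005, 0.002, 0.001, 0.001),
                   q = c(0.05, 0.20, 0.09, 0.01, 0.01, 0.01))
  calls <- call_de(fc, st)
  expect_equal(calls$call, c("down", "none", "down", "up", "none", "none"))
  # exactly the two engineered rows pass in a 6-gene toy
  expect_equal(sum(calls$call == "down"), 2L)
  expect_error(call_de(fc[1:3, ], st), "misaligned")
  # q computed internally by BH when absent
  calls2 <- call_de(fc, st[, c("gene", "condition", "p")])
  expect_equal(calls2$q, bh_fdr(st$p))
})
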