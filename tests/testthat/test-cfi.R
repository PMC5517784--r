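make_fc <- function(r, cond = "t") {
  data.frame(gene = names(r), condition = cond, r = unname(r),
             stringsAsFactors = FALSE)
}
make_calls <- function(call, cond = "t") {
  data.frame(gene = names(call), condition = cond, call = unname(call),
             stringsAsFactors = FALSE)
}

test_that("pathway CFI is the product over significantly changed members", {
  fc <- make_fc(c(a = 0.5, b = 0.5, c = 0.9, d = 3))
  calls <- make_calls(c(a = "down", b = "down", c = "none", d = "none"))
  expect_equal(pathway_cfi(fc, calls, c("a", "b", "c"), "t"), 0.25)
  # no member changed: empty product = 1
  none <- make_calls(c(a = "none", b = "none", c = "none", d = "none"))
  expect_equal(pathway_cfi(fc, none, c("a", "b", "c"), "t"), 1)
  # an up-called member contributes its r > 1
  up <- make_calls(c(a = "down", b = "none", c = "none", d = "up"))
  expect_equal(pathway_cfi(fc, up, c("a", "d"), "t"), 0.5 * 3)
  # permutation invariance over member order
  expect_equal(pathway_cfi(fc, calls, c("c", "b", "a"), "t"),
               pathway_cfi(fc, calls, c("a", "b", "c"), "t"))
  expect_error(pathway_cfi(fc, calls, c("a", "zz"), "t"), "zz")
  expect_error(pathway_cfi(fc, calls, c("a", "a"), "t"), "duplicated")
  expect_error(pathway_cfi(fc, calls, character(0), "t"), "non-empty")
})

test_that("adding or deepening a downregulation strictly lowers the CFI", {
  fc <- make_fc(c(a = 0.5, b = 0.4, c = 0.8))
  base <- pathway_cfi(fc, make_calls(c(a = "down", b = "none", c = "none")),
                      c("a", "b", "c"), "t")
  more <- pathway_cfi(fc, make_calls(c(a = "down", b = "down", c = "none")),
                      c("a", "b", "c"), "t")
  expect_lt(more, base)
  deeper <- make_fc(c(a = 0.3, b = 0.4, c = 0.8))
  expect_lt(pathway_cfi(deeper, make_calls(c(a = "down", b = "none", c = "none")),
                        c("a", "b", "c"), "t"), base)
})

test_that("total CFI multiplies pathway values and matches published rows", {
  expect_equal(signif(total_cfi(c(0.0047, 0.0024, 0.017)), 2), 1.9e-07)
  expect_equal(signif(total_cfi(c(0.0033, 0.5400, 0.0728)), 2), 1.3e-04)
  expect_equal(signif(total_cfi(c(0.0013, 0.0055, 0.0149)), 2), 1.1e-07)
  expect_equal(total_cfi(c(1, 1, 1)), 1)
  expect_equal(total_cfi(0.25), 0.25)
  # permutation invariance over pathway order
  expect_equal(total_cfi(c(0.017, 0.0047, 0.0024)),
               total_cfi(c(0.0047, 0.0024, 0.017)))
  expect_error(total_cfi(numeric(0)), "at least one")
  expect_error(total_cfi(c(0.5, 0)), "> 0")
})

test_that("conditions rank ascending by total CFI with lexicographic ties", {
  totals <- c("G+/M-" = 1.3e-04, "G+/M+" = 1.9e-07, "Med" = 7.9e-07,
              "PPMS" = 1.3e-04, "NMO" = 1.1e-07)
  rk <- rank_conditions(totals)
  expect_equal(rk$condition, c("NMO", "G+/M+", "Med", "G+/M-", "PPMS"))
  expect_equal(rk$rank, c(1L, 2L, 3L, 4L, 4L))
  one <- rank_conditions(c(solo = 0.5))
  expect_equal(nrow(one), 1L)
})

test_that("cfi_table aggregates calls per condition and pathway", {
  fc <- rbind(make_fc(c(a = 0.5, b = 0.25, c = 2.0), "t1"),
              make_fc(c(a = 1.0, b = 0.9, c = 1.1), "t2"))
  calls <- rbind(make_calls(c(a = "down", b = "down", c = "up"), "t1"),
                 make_calls(c(a = "none", b = "none", c = "none"), "t2"))
  pw <- list(p1 = c("a", "b"), p2 = "c")
  tab <- cfi_table(fc, calls, pw)
  expect_equal(tab$cfi[tab$condition == "t1" & tab$pathway == "p1"], 0.125)
  expect_equal(tab$cfi[tab$condition == "t1" & tab$pathway == "p2"], 2.0)
  expect_true(all(tab$cfi[tab$condition == "t2"] == 1))
  totals <- attr(tab, "totals")
  expect_equal(totals$total_cfi[totals$condition == "t1"], 0.25)
  expect_equal(tab$n_down[tab$condition == "t1" & tab$pathway == "p1"], 2L)
  expect_equal(tab$n_up[tab$condition == "t1" & tab$pathway == "p2"], 1L)
})

test_that("summary-table gene aliases map onto panel ids", {
  expect_equal(unname(apply_aliases(c("Eno", "Pdh", "Sdhaf2", "Hprt1", "Gpi"))),
               c("Eno1", "Pdha1", "Sdh", "Hprt", "Gpi"))
  panels <- scenario_panels()
  expect_true(all(apply_aliases(c("Eno", "Pgam", "Pdh", "Sdhaf2")) %in%
                    unlist(panels)))
})

test_that("totals format the way summary tables print them", {
  expect_equal(format_cfi_total(total_cfi(c(0.0047, 0.0024, 0.017))), "1.9E-07")
  expect_equal(format_cfi_total(1.2974e-04), "1.3E-04")
})
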