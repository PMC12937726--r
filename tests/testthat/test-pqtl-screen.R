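t2 <- read_summary_stats(acemod_fixture("table2"))

test_that("the typeset number dialects parse", {
  expect_equal(parse_stat_number("3.306 × 10^−291"), 3.306e-291)
  expect_equal(parse_stat_number("−1.217"), -1.217)
  expect_equal(parse_stat_number(c("0.05", "6.8e-15", "junk")),
               c(0.05, 6.8e-15, NA))
  expect_equal(t2$beta[t2$variant_id == "rs3730025"], -1.217)
  expect_equal(t2$p_value[t2$variant_id == "rs3730025"], 3.306e-291)
})

test_that("candidate filter applies p, consequence and inclusive beta floor", {
  th <- screen_thresholds()
  keep <- filter_candidates(make_stats(beta = 0.351, p_value = 5.356e-105), th)
  expect_equal(nrow(keep), 1L)
  expect_equal(nrow(filter_candidates(make_stats(beta = 0.350), th)), 1L) # inclusive
  expect_equal(nrow(filter_candidates(make_stats(beta = 0.349, p_value = 1e-10), th)), 0L)
  expect_equal(nrow(filter_candidates(make_stats(beta = -1.217, p_value = 0.06), th)), 0L)
  expect_equal(nrow(filter_candidates(make_stats(consequence = "intronic"), th)), 0L)
  # malformed records are skipped with a message, not an error
  bad <- make_stats(variant_id = c("a", "b"), beta = c("oops", "0.5"),
                    p_value = c("1e-9", "1e-9"))
  expect_message(out <- filter_candidates(bad, th), "skipped")
  expect_equal(out$variant_id, "b")
  # idempotent and order-preserving
  expect_identical(filter_candidates(t2, th), filter_candidates(filter_candidates(t2, th), th))
})

test_that("Bonferroni and large-effect cuts use strict boundaries", {
  th <- screen_thresholds()
  expect_equal(nrow(bonferroni_select(make_stats(p_value = 3e-7), th)), 0L)
  expect_equal(nrow(bonferroni_select(make_stats(p_value = 2.9e-7), th)), 1L)
  expect_equal(nrow(bonferroni_select(make_stats()[0, ], th)), 0L)
  expect_equal(nrow(large_effect_subset(make_stats(beta = 1.000), th)), 0L)
  expect_equal(nrow(large_effect_subset(make_stats(beta = -1.217), th)), 1L)
  expect_equal(nrow(large_effect_subset(make_stats(beta = 0.505), th)), 0L)
})

test_that("cascade is monotone in its thresholds and filters commute", {
  set.seed(31)
  tab <- generate_pqtl_table(400, data.frame(
    variant_id = sprintf("pl%d", 1:4), gene = sprintf("G%d", 1:4),
    beta = c(1.2, -1.5, 0.4, -0.36), carrier_fraction = c(0.02, 0.05, 0.1, 0.2)),
    n_samples = 35559, seed = 31)
  th1 <- screen_thresholds()
  th2 <- screen_thresholds(beta_abs_min = 0.5)
  th3 <- screen_thresholds(nominal_p = 0.01)
  expect_lte(nrow(filter_candidates(tab, th2)), nrow(filter_candidates(tab, th1)))
  expect_lte(nrow(filter_candidates(tab, th3)), nrow(filter_candidates(tab, th1)))
  a <- bonferroni_select(filter_candidates(tab, th1), th1)
  b <- filter_candidates(bonferroni_select(tab, th1), th1)
  expect_equal(a$variant_id, b$variant_id)
})

test_that("planted effects are recovered exactly from a simulated table", {
  planted <- data.frame(variant_id = sprintf("rsPL%02d", 1:6),
                        gene = sprintf("PG%02d", 1:6),
                        beta = c(1.2, -1.5, 2.0, -1.05, 1.8, -2.5),
                        carrier_fraction = rep(c(0.05, 0.1), 3))
  tab <- generate_pqtl_table(10000, planted, n_samples = 35559, seed = 77)
  hits <- bonferroni_select(tab, screen_thresholds())
  expect_setequal(hits$variant_id, planted$variant_id)
})

test_that("control-based refinement removes only normal-range carriers", {
  records <- make_stats(variant_id = c("v1", "v2", "v3"),
                        gene = c("A", "B", "C"), beta = c(0.5, -0.7, 1.1))
  calls <- matrix(0L, nrow = 2, ncol = 3,
                  dimnames = list(c("c1", "c2"), c("v1", "v2", "v3")))
  calls["c1", "v1"] <- 1L   # carried by a control at 95% (normal)
  calls["c2", "v2"] <- 2L   # carried only by a control at 40% (outside)
  gm <- genotype_matrix(calls)
  pct <- c(c1 = 95, c2 = 40)
  out <- refine_by_controls(records, gm, pct)
  expect_setequal(out$variant_id, c("v2", "v3"))
  expect_equal(attr(out, "excluded")$variant_id, "v1")
  # no carriage at all: list unchanged; re-application is a no-op
  empty_gm <- genotype_matrix(matrix(0L, 2, 3, dimnames = dimnames(calls)))
  expect_equal(refine_by_controls(records, empty_gm, pct)$variant_id,
               records$variant_id)
  again <- refine_by_controls(out, gm, pct)
  expect_equal(again$variant_id, out$variant_id)
  # controls without phenotype contribute no evidence
  expect_message(keep <- refine_by_controls(records, gm, c(c1 = NA, c2 = 40)),
                 "without phenotype")
  expect_equal(nrow(keep), 3L)
})

test_that("gene summaries count cis, trans and singletons", {
  gs <- summarize_genes(t2)
  expect_equal(gs$n_variants, 17L)
  expect_equal(gs$n_genes, 12L)
  expect_equal(gs$n_cis, 4L)
  expect_equal(gs$n_singleton_trans, 10L)
  expect_equal(summarize_genes(t2[0, ])$n_genes, 0L)
  three <- make_stats(variant_id = c("a", "b", "c"), gene = "SAME")
  expect_equal(summarize_genes(three)$n_genes, 1L)
  expect_equal(summarize_genes(three)$n_singleton_trans, 0L)
})
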