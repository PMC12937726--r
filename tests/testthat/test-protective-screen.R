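test_that("variant QC filters call rate first, then folded MAF", {
  calls <- matrix(0L, nrow = 100, ncol = 4,
                  dimnames = list(sprintf("s%03d", 1:100), c("ok", "miss", "rare", "edge")))
  calls[1:30, "ok"] <- 1L
  calls[1:30, "miss"] <- 1L; calls[31:36, "miss"] <- NA_integer_  # 6% missing
  calls[1:4, "rare"] <- 1L                                        # MAF 0.02
  calls[1:10, "edge"] <- 1L                                       # MAF exactly 0.05
  gm <- genotype_matrix(calls)
  out <- variant_qc(gm)
  expect_setequal(colnames(out$calls), c("ok", "edge"))
  expect_equal(unname(attr(out, "qc_counts")),
               c(1L, 1L, 2L), ignore_attr = TRUE)
  # identity on a clean matrix
  clean <- genotype_matrix(calls[, c("ok", "edge")])
  expect_equal(colnames(variant_qc(clean)$calls), c("ok", "edge"))
  # folded MAF: an almost-fixed alt allele is rare after folding
  fixed <- matrix(2L, nrow = 100, ncol = 1, dimnames = list(rownames(calls), "hom"))
  fixed[1:2] <- 1L
  expect_warning(res <- variant_qc(genotype_matrix(fixed)), "all variants removed")
  expect_equal(ncol(res$calls), 0L)
})

test_that("allelic test matches the closed form and its oracle", {
  # hand-checked example: allele table (10,90; 30,70), n = 200 -> chi2 = 12.5
  # 5 het + .. produce 10 minor alleles among 50 high samples etc.
  calls <- matrix(0L, nrow = 100, ncol = 1,
                  dimnames = list(sprintf("s%03d", 1:100), "v1"))
  calls[1:10, 1] <- 1L    # high group: 10 minor alleles / 100
  calls[51:78, 1] <- 1L   # low group: 28 het
  calls[79, 1] <- 2L      # + 1 hom = 30 minor alleles / 100
  group <- setNames(rep(c("high", "low"), each = 50), rownames(calls))
  res <- allelic_test(genotype_matrix(calls, group = group))
  expect_equal(res$chi_square, 12.5)
  expect_equal(res$p_value, pchisq(12.5, 1, lower.tail = FALSE))
  expect_equal(res$odds_ratio, (10 * 70) / (90 * 30))

  # 1000 random tables against the independent chisq.test oracle
  set.seed(101)
  for (i in 1:1000) {
    tab <- matrix(sample(0:40, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    ours <- acemod:::chisq_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$chi_square
    oracle <- suppressWarnings(
      chisq.test(tab, correct = FALSE)$statistic)
    expect_equal(ours, unname(oracle), tolerance = 1e-10)
  }

  # identical allele frequencies -> chi2 = 0, p = 1
  eq <- matrix(rep(c(1L, 0L), 50), ncol = 1,
               dimnames = list(sprintf("s%03d", 1:100), "v"))
  expect_equal(allelic_test(genotype_matrix(eq, group = group))$chi_square, 0)
  # zero margin -> chi2 = 0 by convention, logged
  mono <- matrix(0L, 100, 1, dimnames = list(rownames(calls), "v"))
  expect_message(res0 <- allelic_test(genotype_matrix(mono, group = group)),
                 "zero allele-table margin")
  expect_equal(res0$chi_square, 0)
  expect_equal(res0$p_value, 1)
})

test_that("genomic inflation follows the median chi-square definition", {
  expect_equal(suppressWarnings(genomic_inflation(rep(0.4549364, 5))), 1)
  expect_equal(suppressWarnings(genomic_inflation(rep(0.9098728, 5))), 2)
  expect_warning(genomic_inflation(rep(1, 5)), "unstable")
  expect_error(genomic_inflation(numeric(0)), "no test statistics")
})

test_that("Bonferroni adjustment multiplies and caps", {
  res <- data.frame(variant_id = letters[1:10], chi_square = 1,
                    p_value = c(0.01, 0.5, rep(0.2, 8)))
  adj <- bonferroni_adjust(res)
  expect_equal(adj$adjusted_p[1:2], c(0.1, 1.0))
  one <- bonferroni_adjust(res[1, ])
  expect_equal(one$adjusted_p, one$p_value)
})

test_that("exclusivity equals the brute-force double loop", {
  grid <- read_genotype_grid()
  expect_setequal(exclusive_variants(grid), exclusive_oracle(grid))
  set.seed(202)
  for (i in 1:60) {
    gm <- random_matrix(sample(5:20, 1), sample(10:50, 1),
                        missing_rate = sample(c(0, 0.1), 1))
    expect_identical(sort(exclusive_variants(gm)), sort(exclusive_oracle(gm)))
  }
  # explicit boundary cases
  calls <- matrix(0L, 4, 2, dimnames = list(c("h1", "h2", "l1", "l2"), c("a", "b")))
  calls[c("h1", "h2"), "a"] <- 1L          # high only -> exclusive
  calls[c("h1", "l1"), "b"] <- 1L          # both groups -> not exclusive
  gm <- genotype_matrix(calls, group = c(h1 = "high", h2 = "high",
                                         l1 = "low", l2 = "low"))
  expect_equal(exclusive_variants(gm), "a")
})

test_that("recurrence window keeps 3-5 carriers and respects subsets", {
  gm <- generate_genotype_matrix(15, 44, n_background_variants = 0,
                                 planted_exclusive = 10,
                                 recurrence_range = c(1, 8), seed = 5)
  excl <- exclusive_variants(gm)
  rec <- recurrence_filter(gm, excl, window = c(3, 5))
  counts <- colSums(gm$calls[gm$group == "high", excl, drop = FALSE] >= 1)
  expect_setequal(rec$variant_id, excl[counts >= 3 & counts <= 5])
  expect_true(all(rec$variant_id %in% excl))
  # widening the window never shrinks the output; [1, n_high] is a no-op
  wide <- recurrence_filter(gm, excl, window = c(1, 15))
  expect_setequal(wide$variant_id, excl)
  expect_true(all(rec$variant_id %in% wide$variant_id))
  expect_error(recurrence_filter(gm, excl, window = c(0, 5)), "invalid")
})

test_that("null simulation is calibrated: type-I error and lambda", {
  # scaled-down null scan (full 59 x 10,000 runs in the acceptance suite)
  set.seed(303)
  n <- 59
  nv <- 3000
  maf <- runif(nv, 0.05, 0.5)
  calls <- vapply(maf, function(m) rbinom(n, 2L, m), integer(n))
  dimnames(calls) <- list(sprintf("s%02d", 1:n), sprintf("v%04d", 1:nv))
  group <- setNames(rep(c("high", "low"), c(15, 44)), rownames(calls))
  res <- allelic_test(genotype_matrix(calls, group = group))
  expect_lt(abs(mean(res$p_value < 0.05) - 0.05), 0.015)
  expect_gt(genomic_inflation(res), 0.85)
  expect_lt(genomic_inflation(res), 1.15)
})

test_that("the full screen recovers planted truth end to end", {
  gm <- generate_genotype_matrix(15, 44, n_background_variants = 150,
                                 planted_exclusive = 12, missing_rate = 0,
                                 seed = 7)
  res <- protective_screen(gm)
  planted <- grep("^pl", colnames(gm$calls), value = TRUE)
  expect_setequal(res$recurrent$variant_id, planted)
  expect_equal(unname(res$counts["n_recurrent"]), 12L)
  expect_gt(res$lambda_gc, 0)
  # the MAF-first ordering loses planted variants (3-5 carriers of 59 is
  # below 5% MAF unless homozygotes pad the allele count)
  strict <- protective_screen(gm, maf_before_exclusive = TRUE)
  expect_true(all(strict$recurrent$variant_id %in% planted))
  expect_lt(nrow(strict$recurrent), length(planted))
})
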