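# Shared builders for small in-code fixtures.

# A minimal summary-stat frame; defaults pass every cascade stage.
make_stats <- function(variant_id = "rsX", gene = "GENEX", beta = 1.5,
                       p_value = 1e-10, consequence = "missense", maf = 0.1) {
  out <- data.frame(variant_id = variant_id, gene = gene,
                    consequence = consequence, beta = beta,
                    p_value = p_value, maf = maf, stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

# Random grouped genotype matrix for property tests.
random_matrix <- function(n_samples, n_variants, missing_rate = 0) {
  calls <- matrix(sample(c(0L, 0L, 0L, 1L, 2L), n_samples * n_variants,
                         replace = TRUE),
                  nrow = n_samples,
                  dimnames = list(sprintf("s%03d", seq_len(n_samples)),
                                  sprintf("v%04d", seq_len(n_variants))))
  if (missing_rate > 0)
    calls[runif(length(calls)) < missing_rate] <- NA_integer_
  group <- setNames(sample(c("high", "low"), n_samples, replace = TRUE),
                    rownames(calls))
  # ensure both groups are present
  group[1] <- "high"; group[n_samples] <- "low"
  genotype_matrix(calls, group = group)
}

# Brute-force double-loop oracle for the exclusivity screen.
exclusive_oracle <- function(gm) {
  out <- character(0)
  hi <- names(gm$group)[gm$group == "high"]
  lo <- names(gm$group)[gm$group == "low"]
  for (v in colnames(gm$calls)) {
    in_high <- FALSE
    in_low <- FALSE
    for (s in hi) {
      x <- gm$calls[s, v]
      if (!is.na(x) && x >= 1) in_high <- TRUE
    }
    for (s in lo) {
      x <- gm$calls[s, v]
      if (!is.na(x) && x >= 1) in_low <- TRUE
    }
    if (in_high && !in_low) out <- c(out, v)
  }
  out
}
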