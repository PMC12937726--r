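#' Sample-by-variant genotype matrix
#'
#' Container for carrier states: an integer matrix of alt-allele dosages
#' (0 = ref, 1 = het, 2 = hom, `NA` = missing) with sample IDs as row names
#' and variant IDs as column names, plus an optional high/low group label
#' per sample and gene symbol per variant.
#'
#' @param calls integer matrix, samples x variants, values in `{0,1,2,NA}`.
#' @param group named character vector (`"high"`/`"low"`) over sample IDs,
#'   or NULL.
#' @param gene_of named character vector over variant IDs, or NULL.
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(calls, group = NULL, gene_of = NULL) {
  # a zero-column subset legitimately carries no variant names
  if (!is.matrix(calls) || is.null(rownames(calls)) ||
      (ncol(calls) > 0 && is.null(colnames(calls))))
    stop("calls must be a matrix with sample and variant dimnames", call. = FALSE)
  storage.mode(calls) <- "integer"
  if (any(!(calls %in% c(0L, 1L, 2L, NA))))
    stop("calls must be 0/1/2/NA dosages", call. = FALSE)
  if (anyDuplicated(rownames(calls)))
    stop("duplicated sample IDs", call. = FALSE)
  if (!is.null(group)) {
    group <- group[rownames(calls)]
    if (any(is.na(group)) || !all(group %in% c("high", "low")))
      stop("every sample must be grouped high or low", call. = FALSE)
  }
  if (!is.null(gene_of)) gene_of <- gene_of[colnames(calls)]
  structure(list(calls = calls, group = group, gene_of = gene_of),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls), "variants\n")
  if (!is.null(x$group)) print(table(x$group))
  invisible(x)
}

subset_variants <- function(gm, keep) {
  genotype_matrix(gm$calls[, keep, drop = FALSE], group = gm$group,
                  gene_of = gm$gene_of)
}

#' Variant-level quality control: call rate then minor allele frequency
#'
#' Drops variants whose missing-call fraction exceeds `max_missing`, then
#' variants whose folded MAF (computed on non-missing calls, two alleles per
#' sample) falls below `min_maf`; a MAF exactly at the threshold is retained.
#' Order matters and matches the reference pipeline: call-rate filter first.
#'
#' @param matrix a [genotype_matrix()].
#' @param max_missing maximum missing-call fraction (default 0.05).
#' @param min_maf minimum folded MAF (default 0.05); set 0 to disable.
#' @return the filtered matrix, with a `qc_counts` attribute
#'   (`removed_callrate`, `removed_maf`, `retained`).
#' @export
variant_qc <- function(matrix, max_missing = 0.05, min_maf = 0.05) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  calls <- matrix$calls
  if (ncol(calls) == 0) stop("empty genotype matrix", call. = FALSE)
  miss_frac <- colMeans(is.na(calls))
  keep1 <- miss_frac <= max_missing
  calls1 <- calls[, keep1, drop = FALSE]
  maf <- folded_maf(calls1)
  keep2 <- maf >= min_maf
  out <- subset_variants(matrix, colnames(calls1)[keep2])
  if (ncol(out$calls) == 0) warning("all variants removed by QC", call. = FALSE)
  attr(out, "qc_counts") <- c(removed_callrate = sum(!keep1),
                              removed_maf = sum(!keep2),
                              retained = sum(keep2))
  out
}

folded_maf <- function(calls) {
  nonmiss <- colSums(!is.na(calls))
  alt <- colSums(calls, na.rm = TRUE)
  af <- ifelse(nonmiss > 0, alt / (2 * nonmiss), 0)
  pmin(af, 1 - af)
}

#' Basic allelic association test (2 x 2 allele counts, 1-df chi-square)
#'
#' For each variant, folds to the minor allele across all non-missing calls
#' and builds the minor/major x high/low allele-count table. The statistic
#' is the closed-form chi-square without continuity correction,
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`; any zero margin gives
#' chi-square 0 and p 1 by convention (logged). The odds ratio `ad/bc` is
#' `NA` when any cell is zero.
#'
#' @param matrix a grouped [genotype_matrix()].
#' @return data.frame (class `assoc_result`): `variant_id`, `chi_square`,
#'   `p_value`, `odds_ratio`.
#' @export
allelic_test <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (is.null(matrix$group)) stop("matrix must be grouped", call. = FALSE)
  calls <- matrix$calls
  hi <- matrix$group == "high"
  nonmiss_hi <- colSums(!is.na(calls[hi, , drop = FALSE]))
  nonmiss_lo <- colSums(!is.na(calls[!hi, , drop = FALSE]))
  alt_hi <- colSums(calls[hi, , drop = FALSE], na.rm = TRUE)
  alt_lo <- colSums(calls[!hi, , drop = FALSE], na.rm = TRUE)
  tot_alt <- alt_hi + alt_lo
  tot_alleles <- 2 * (nonmiss_hi + nonmiss_lo)
  flip <- tot_alleles > 0 & tot_alt / pmax(tot_alleles, 1L) > 0.5
  a <- ifelse(flip, 2 * nonmiss_hi - alt_hi, alt_hi)   # minor, high
  c_ <- ifelse(flip, 2 * nonmiss_lo - alt_lo, alt_lo)  # minor, low
  b <- 2 * nonmiss_hi - a                              # major, high
  d <- 2 * nonmiss_lo - c_                             # major, low
  chi <- chisq_2x2(a, b, c_, d)
  degenerate <- sum(chi$degenerate)
  if (degenerate > 0)
    message(degenerate, " variant(s) with a zero allele-table margin: chi-square set to 0")
  or <- ifelse(a > 0 & b > 0 & c_ > 0 & d > 0, (a * d) / (b * c_), NA_real_)
  out <- data.frame(
    variant_id = colnames(calls),
    chi_square = chi$chi_square,
    p_value = stats::pchisq(chi$chi_square, df = 1, lower.tail = FALSE),
    odds_ratio = or,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Closed-form 2 x 2 chi-square without continuity correction
#' @keywords internal
chisq_2x2 <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  degenerate <- denom == 0
  chi <- ifelse(degenerate, 0, n * (a * d - b * c_)^2 / ifelse(degenerate, 1, denom))
  list(chi_square = chi, degenerate = degenerate)
}

#' Genomic inflation factor from median chi-square
#'
#' `lambda = median(chi-square) / 0.4549364`, the median of the 1-df
#' chi-square distribution. Values near 1 indicate well-calibrated tests.
#'
#' @param results an `assoc_result` data.frame or numeric chi-square vector.
#' @return `lambda_gc`, a positive scalar.
#' @export
genomic_inflation <- function(results) {
  chi <- if (is.data.frame(results)) results$chi_square else results
  if (length(chi) == 0) stop("no test statistics supplied", call. = FALSE)
  if (length(chi) < 100)
    warning("fewer than 100 statistics; lambda estimate is unstable", call. = FALSE)
  stats::median(chi) / 0.4549364
}

#' Bonferroni adjustment of association p-values
#'
#' @param results an `assoc_result` data.frame.
#' @return the input with an `adjusted_p = min(1, p * m)` column.
#' @export
bonferroni_adjust <- function(results) {
  m <- nrow(results)
  if (m < 1) stop("need at least one test", call. = FALSE)
  results$adjusted_p <- pmin(1, results$p_value * m)
  results
}

#' Variants carried exclusively in the high-ACE group
#'
#' Returns variants with at least one carrier (het or hom) among high-group
#' samples and zero carriers among low-group samples. Missing calls are not
#' carriage.
#'
#' @param matrix a grouped [genotype_matrix()].
#' @return character vector of variant IDs.
#' @export
exclusive_variants <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (is.null(matrix$group)) stop("matrix must be grouped", call. = FALSE)
  hi <- matrix$group == "high"
  carrier <- matrix$calls >= 1L
  n_hi <- colSums(carrier[hi, , drop = FALSE], na.rm = TRUE)
  n_lo <- colSums(carrier[!hi, , drop = FALSE], na.rm = TRUE)
  colnames(matrix$calls)[n_hi >= 1L & n_lo == 0L]
}

#' Recurrence filter over exclusive variants
#'
#' Keeps variants whose high-group carrier count (individuals; homozygotes
#' counted once) lies inside the window, discarding stochastic singletons.
#'
#' @param matrix a grouped [genotype_matrix()].
#' @param exclusive variant IDs from [exclusive_variants()].
#' @param window `c(min, max)` carrier counts (default `c(3, 5)`).
#' @return data.frame `variant_id`, `carrier_count`, `gene`, with an
#'   `n_genes` attribute counting unique genes.
#' @export
recurrence_filter <- function(matrix, exclusive, window = c(3L, 5L)) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (window[1] < 1 || window[1] > window[2])
    stop("invalid recurrence window", call. = FALSE)
  hi <- matrix$group == "high"
  calls <- matrix$calls[hi, exclusive, drop = FALSE]
  counts <- colSums(calls >= 1L, na.rm = TRUE)
  keep <- counts >= window[1] & counts <= window[2]
  genes <- if (is.null(matrix$gene_of)) rep(NA_character_, sum(keep))
           else unname(matrix$gene_of[exclusive[keep]])
  out <- data.frame(variant_id = exclusive[keep],
                    carrier_count = as.integer(counts[keep]),
                    gene = genes,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_genes") <- length(unique(out$gene[!is.na(out$gene)]))
  out
}

#' End-to-end protective-variant screen
#'
#' Call-rate QC, allelic association with genomic inflation, Bonferroni
#' adjustment, the exclusivity screen and the recurrence filter. Because
#' variants recurring in 3-5 of a small high group rarely reach 5% MAF,
#' the exclusivity screen by default runs before the MAF filter
#' (`maf_before_exclusive = FALSE`); the association scan always uses the
#' fully QC'd (MAF-filtered) matrix.
#'
#' @param matrix a grouped [genotype_matrix()].
#' @param max_missing,min_maf QC thresholds, see [variant_qc()].
#' @param window recurrence window, see [recurrence_filter()].
#' @param maf_before_exclusive apply the MAF filter before the exclusivity
#'   screen as well (default FALSE).
#' @return list with `qc_counts`, `association`, `lambda_gc`, `exclusive`,
#'   `recurrent` and a `counts` summary.
#' @export
protective_screen <- function(matrix, max_missing = 0.05, min_maf = 0.05,
                              window = c(3L, 5L), maf_before_exclusive = FALSE) {
  qc_call <- variant_qc(matrix, max_missing = max_missing, min_maf = 0)
  qc_full <- variant_qc(qc_call, max_missing = 1, min_maf = min_maf)
  assoc <- bonferroni_adjust(allelic_test(qc_full))
  lambda <- genomic_inflation(assoc)
  excl_matrix <- if (maf_before_exclusive) qc_full else qc_call
  excl <- exclusive_variants(excl_matrix)
  rec <- recurrence_filter(excl_matrix, excl, window = window)
  list(
    qc_counts = c(attr(qc_call, "qc_counts")[c("removed_callrate", "retained")],
                  after_maf = unname(attr(qc_full, "qc_counts")["retained"])),
    association = assoc,
    lambda_gc = lambda,
    exclusive = excl,
    recurrent = rec,
    counts = c(n_exclusive = length(excl), n_recurrent = nrow(rec),
               n_genes = attr(rec, "n_genes"))
  )
}
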