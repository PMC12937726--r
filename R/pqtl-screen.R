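#' Thresholds for the pQTL filtering cascade
#'
#' Defaults follow the calibrated screen over the Icelandic plasma-ACE
#' summary statistics: nominal significance p < 0.05, effect-size floor
#' |beta| >= 0.350 (inclusive; calibrated on the ABO blood-group variants),
#' exome-wide Bonferroni p < 3e-7 (strict), and a large-effect cut
#' |beta| > 1.000 (strict).
#'
#' @param nominal_p nominal p-value threshold (strict `<`).
#' @param beta_abs_min minimum absolute beta (inclusive `>=`).
#' @param bonferroni_p exome-wide threshold (strict `<`).
#' @param large_beta_abs large-effect cut (strict `>`).
#' @param coding_classes consequence classes counted as protein-coding.
#' @return a `screen_thresholds` list.
#' @export
screen_thresholds <- function(nominal_p = 0.05, beta_abs_min = 0.350,
                              bonferroni_p = 3e-7, large_beta_abs = 1.000,
                              coding_classes = c("missense", "stop_gained",
                                                 "inframe_indel", "frameshift")) {
  if (!(bonferroni_p < nominal_p))
    stop("bonferroni_p must be below nominal_p", call. = FALSE)
  if (!(large_beta_abs > beta_abs_min))
    stop("large_beta_abs must exceed beta_abs_min", call. = FALSE)
  structure(list(nominal_p = nominal_p, beta_abs_min = beta_abs_min,
                 bonferroni_p = bonferroni_p, large_beta_abs = large_beta_abs,
                 coding_classes = coding_classes),
            class = "screen_thresholds")
}

#' Parse p-values and betas in the dialects the source tables print
#'
#' Handles plain numerics, scientific notation, the typeset form
#' `"3.306 x 10^-291"` with a multiplication sign and caret exponent, and
#' Unicode minus signs.
#'
#' @param x character or numeric vector.
#' @return numeric vector; unparseable entries become `NA`.
#' @export
parse_stat_number <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- gsub("−", "-", x)               # Unicode minus
  x <- gsub("[×✕x*]\\s*10\\^?", "e", x) # "x 10^" dialects
  x <- gsub("[\\^\\s]", "", x, perl = TRUE)
  suppressWarnings(as.numeric(x))
}

#' Nominal-significance / coding / effect-size candidate filter
#'
#' Retains records with `p < nominal_p`, a protein-coding consequence and
#' `|beta| >= beta_abs_min`. Records with malformed beta or p are skipped
#' with a logged count. Order is preserved and the operation is idempotent.
#'
#' @param records a `summary_stats` data.frame.
#' @param thresholds a [screen_thresholds()].
#' @return the retained records.
#' @export
filter_candidates <- function(records, thresholds = screen_thresholds()) {
  beta <- parse_stat_number(records$beta)
  p <- parse_stat_number(records$p_value)
  bad <- is.na(beta) | is.na(p)
  if (any(bad)) message(sum(bad), " record(s) skipped: malformed beta or p-value")
  keep <- !bad & p < thresholds$nominal_p &
    records$consequence %in% thresholds$coding_classes &
    abs(beta) >= thresholds$beta_abs_min
  records[keep, , drop = FALSE]
}

#' Exome-wide Bonferroni selection
#'
#' Retains records with `p < bonferroni_p` (strict). The returned object
#' carries `n_variants` and `n_genes` attributes.
#'
#' @inheritParams filter_candidates
#' @return the retained records.
#' @export
bonferroni_select <- function(records, thresholds = screen_thresholds()) {
  p <- parse_stat_number(records$p_value)
  out <- records[!is.na(p) & p < thresholds$bonferroni_p, , drop = FALSE]
  attr(out, "n_variants") <- nrow(out)
  attr(out, "n_genes") <- length(unique(out$gene))
  out
}

#' Large-effect sublist (|beta| strictly above the cut)
#'
#' @inheritParams filter_candidates
#' @return the retained records.
#' @export
large_effect_subset <- function(records, thresholds = screen_thresholds()) {
  beta <- parse_stat_number(records$beta)
  records[!is.na(beta) & abs(beta) > thresholds$large_beta_abs, , drop = FALSE]
}

#' Remove list variants carried by phenotypically normal controls
#'
#' A modifier candidate carried (het or hom) by at least one control subject
#' whose genotype-corrected ACE percent lies inside the normal range is an
#' artifact and is excluded. Controls without a phenotype contribute no
#' evidence and are logged. Missing genotypes are not evidence of carriage.
#'
#' @param records a `summary_stats` data.frame (the candidate list).
#' @param control_matrix a [genotype_matrix()] over control subjects.
#' @param control_percent named numeric vector of corrected ACE percents,
#'   names matching `control_matrix` sample IDs.
#' @param normal_range `c(low, high)` percent window counted as normal
#'   (default `c(50, 150)`, inclusive).
#' @return the refined list, with an `excluded` attribute naming each
#'   removed variant and its normal-carrier count.
#' @export
refine_by_controls <- function(records, control_matrix, control_percent,
                               normal_range = c(50, 150)) {
  stopifnot(inherits(control_matrix, "genotype_matrix"))
  ids <- rownames(control_matrix$calls)
  pct <- control_percent[ids]
  no_pheno <- is.na(pct)
  if (any(no_pheno))
    message(sum(no_pheno), " control(s) without phenotype excluded from evidence")
  normal <- which(!no_pheno & pct >= normal_range[1] & pct <= normal_range[2])
  if (length(normal) == 0 || nrow(records) == 0) {
    attr(records, "excluded") <- data.frame(variant_id = character(),
                                            n_normal_carriers = integer())
    return(records)
  }
  calls <- control_matrix$calls[normal, , drop = FALSE]
  carried <- colSums(calls >= 1L, na.rm = TRUE)
  hit <- records$variant_id %in% names(carried)[carried > 0]
  out <- records[!hit, , drop = FALSE]
  attr(out, "excluded") <- data.frame(
    variant_id = records$variant_id[hit],
    n_normal_carriers = as.integer(carried[records$variant_id[hit]]),
    row.names = NULL
  )
  out
}

#' Gene-level summary of a variant list
#'
#' @param records a `summary_stats` data.frame.
#' @param cis_gene the gene whose variants count as cis-pQTLs (default ACE).
#' @return list with `n_variants`, `n_genes`, `per_gene` counts, `n_cis`,
#'   and `n_singleton_trans` (non-cis genes carrying exactly one variant).
#' @export
summarize_genes <- function(records, cis_gene = "ACE") {
  if (nrow(records) == 0)
    return(list(n_variants = 0L, n_genes = 0L,
                per_gene = integer(), n_cis = 0L, n_singleton_trans = 0L))
  per_gene <- table(records$gene)
  trans <- per_gene[names(per_gene) != cis_gene]
  list(
    n_variants = nrow(records),
    n_genes = length(per_gene),
    per_gene = per_gene,
    n_cis = sum(records$gene == cis_gene),
    n_singleton_trans = sum(trans == 1L)
  )
}
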