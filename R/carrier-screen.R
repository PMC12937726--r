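#' Look up refined-list modifier variants carried by one subject
#'
#' @param carrier_calls named integer vector of dosages (`0/1/2/NA`) for one
#'   subject, names are variant IDs.
#' @param refined_list a `summary_stats` data.frame (the refined modifier
#'   list) with `variant_id`, `gene`, `beta`.
#' @return data.frame of hits (`variant_id`, `gene`, `beta`, `dosage`);
#'   variants off the list are never reported, missing calls are not
#'   carriage.
#' @export
find_modifier_hits <- function(carrier_calls, refined_list) {
  carried <- names(carrier_calls)[!is.na(carrier_calls) & carrier_calls >= 1L]
  hit <- refined_list$variant_id %in% carried
  out <- data.frame(
    variant_id = refined_list$variant_id[hit],
    gene = refined_list$gene[hit],
    beta = parse_stat_number(refined_list$beta[hit]),
    dosage = as.integer(carrier_calls[refined_list$variant_id[hit]]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Phenotype-reliability call for one carrier
#'
#' A carrier with no modifier hits is `concordant`: the measured blood ACE
#' can be trusted to reflect tissue ACE. A positive-beta hit in a subject
#' binned gray/orange/red means the level may be inflated by the modifier
#' (`possible_false_positive`); a negative-beta hit in a blue/yellow subject
#' means the apparent deficiency may be modifier-driven
#' (`possible_false_negative`). Hits whose sign does not oppose the observed
#' bin, or an unknown bin, give `indeterminate`. When hits of both signs are
#' present the bin-opposing sign decides the call and all hits are attached
#' as evidence.
#'
#' @param bin one of blue/yellow/gray/orange/red, or `NA`.
#' @param hits data.frame from [find_modifier_hits()].
#' @return list with `call` and `evidence`.
#' @export
call_phenotype_reliability <- function(bin, hits) {
  bin <- as.character(bin)
  if (nrow(hits) == 0)
    return(list(call = "concordant", evidence = hits))
  if (is.na(bin) || !bin %in% .bin_levels)
    return(list(call = "indeterminate", evidence = hits))
  elevated <- bin %in% c("gray", "orange", "red")
  call <- if (elevated && any(hits$beta > 0)) "possible_false_positive"
          else if (!elevated && any(hits$beta < 0)) "possible_false_negative"
          else "indeterminate"
  list(call = call, evidence = hits)
}

#' Reliability calls for every sample in a genotype matrix
#'
#' @param matrix a [genotype_matrix()] over the carriers.
#' @param phenotype data.frame with `sample_id` and `bin` (a phenotype
#'   report, see [phenotype_report()]).
#' @param refined_list the refined modifier list.
#' @return data.frame with one row per sample: `sample_id`, `n_hits`, `call`.
#' @export
carrier_screen <- function(matrix, phenotype, refined_list) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  ids <- rownames(matrix$calls)
  bins <- phenotype$bin[match(ids, phenotype$sample_id)]
  rows <- lapply(seq_along(ids), function(i) {
    hits <- find_modifier_hits(matrix$calls[i, ], refined_list)
    call <- call_phenotype_reliability(bins[i], hits)
    data.frame(sample_id = ids[i], n_hits = nrow(hits), call = call$call,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Carrier frequency per 100,000 subjects
#'
#' `round(n_carriers / n_subjects * 100000)`, rounding halves away from
#' zero (the convention that reproduces the published cohort table).
#'
#' @param n_carriers,n_subjects counts, `n_carriers <= n_subjects`.
#' @return integer rate per 100,000.
#' @export
carrier_frequency <- function(n_carriers, n_subjects) {
  if (any(n_subjects <= 0)) stop("n_subjects must be positive", call. = FALSE)
  if (any(n_carriers < 0) || any(n_carriers > n_subjects))
    stop("n_carriers must lie in [0, n_subjects]", call. = FALSE)
  as.integer(round_half_up(n_carriers / n_subjects * 1e5))
}

#' APOE genotype summary for a cohort
#'
#' Counts epsilon-4 homozygotes, epsilon-4 heterozygotes and neutral
#' genotypes, with percents of cohort size at one decimal place (halves
#' rounded away from zero).
#'
#' @param genotypes character vector of APOE genotypes, e.g. `"e3/e4"`;
#'   the Greek epsilon is also accepted. Anything unrecognized counts as
#'   unknown.
#' @return data.frame with `class`, `n`, `percent` rows for `e4_homozygote`,
#'   `e4_heterozygote`, `neutral`, `unknown`.
#' @export
apoe_summary <- function(genotypes) {
  g <- gsub("ε", "e", tolower(genotypes))
  known <- c("e2/e2", "e2/e3", "e2/e4", "e3/e3", "e3/e4", "e4/e4")
  g[!g %in% known] <- "unknown"
  hom <- sum(g == "e4/e4")
  het <- sum(g %in% c("e2/e4", "e3/e4"))
  unknown <- sum(g == "unknown")
  neutral <- length(g) - hom - het - unknown
  n <- c(e4_homozygote = hom, e4_heterozygote = het,
         neutral = neutral, unknown = unknown)
  pct <- if (length(g) == 0) rep(0, 4) else round_half_up(100 * n / length(g), 1)
  data.frame(class = names(n), n = as.integer(n), percent = as.numeric(pct),
             row.names = NULL, stringsAsFactors = FALSE)
}
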