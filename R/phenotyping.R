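#' Genotype-correction model for the ACE I/D polymorphism
#'
#' Blood ACE rises with the number of D alleles; DD carriers run about 66%
#' above II carriers. The model holds one positive multiplier per genotype
#' and their Hardy-Weinberg-weighted mean `reference_mean`, the anchor that
#' maps an individual sitting exactly at its genotype-expected mean to 100%.
#'
#' @param factors named multipliers for II, ID, DD; must be strictly
#'   increasing in that order.
#' @param d_allele_freq D-allele frequency used for the HWE weights.
#' @return a `genotype_model` list with `factors` and `reference_mean`.
#' @export
genotype_model <- function(factors = c(II = 1.00, ID = 1.33, DD = 1.66),
                           d_allele_freq = 0.5) {
  if (!all(c("II", "ID", "DD") %in% names(factors)))
    stop("factors must name II, ID and DD", call. = FALSE)
  factors <- factors[c("II", "ID", "DD")]
  if (any(factors <= 0)) stop("factors must be > 0", call. = FALSE)
  if (!(factors["DD"] > factors["ID"] && factors["ID"] > factors["II"]))
    stop("factors must satisfy DD > ID > II", call. = FALSE)
  if (d_allele_freq < 0 || d_allele_freq > 1)
    stop("d_allele_freq must lie in [0,1]", call. = FALSE)
  structure(list(
    factors = factors,
    d_allele_freq = d_allele_freq,
    reference_mean = sum(hwe_weights(d_allele_freq) * factors)
  ), class = "genotype_model")
}

#' Express an assay activity as percent of a control pool
#'
#' @param activity one or more precipitated-activity values.
#' @param control_activities activities of the control set (all positive).
#' @return `activity / mean(control_activities) * 100`.
#' @export
normalize_to_control <- function(activity, control_activities) {
  if (length(control_activities) == 0 || any(!is.finite(control_activities)) ||
      any(control_activities <= 0))
    stop("control activities must be a non-empty positive vector", call. = FALSE)
  activity / mean(control_activities) * 100
}

#' Correct a percent-of-control ACE level for the I/D genotype
#'
#' Multiplicative rescaling `percent * reference_mean / factor(genotype)`.
#' Unknown genotypes are returned unchanged with a warning, flagged
#' uncorrected.
#'
#' @param percent percent-of-control levels.
#' @param genotype character vector of `"II"`, `"ID"`, `"DD"` (anything else
#'   is treated as unknown).
#' @param model a [genotype_model()].
#' @return corrected percents, same length as `percent`.
#' @export
correct_for_genotype <- function(percent, genotype, model = genotype_model()) {
  stopifnot(inherits(model, "genotype_model"))
  genotype <- rep_len(as.character(genotype), length(percent))
  known <- genotype %in% names(model$factors)
  if (any(!known))
    warning(sum(!known), " sample(s) with unknown I/D genotype left uncorrected",
            call. = FALSE)
  out <- percent
  out[known] <- percent[known] * model$reference_mean /
    unname(model$factors[genotype[known]])
  out
}

.bin_levels <- c("blue", "yellow", "gray", "orange", "red")

#' Classify a corrected ACE level into the five phenotype pools
#'
#' Half-open, left-closed intervals: blue `[0,50)`, yellow `[50,80)`,
#' gray `[80,120)`, orange `[120,200)`, red `[200,Inf)`.
#'
#' @param corrected_percent positive corrected levels.
#' @return factor with levels blue/yellow/gray/orange/red.
#' @export
classify_bin <- function(corrected_percent) {
  if (any(!is.finite(corrected_percent)) || any(corrected_percent <= 0))
    stop("corrected_percent must be positive and finite", call. = FALSE)
  cut(corrected_percent, breaks = c(0, 50, 80, 120, 200, Inf),
      labels = .bin_levels, right = FALSE)
}

#' 5B3/1G12 binding ratio, the circulating-mutant marker
#'
#' Both inputs must already be expressed as percent of their own controls.
#' Ratios at or above `threshold` (default 150%, midway between the control
#' ratio and the lowest ratio observed in mutant pools) are flagged
#' mutant-marker-positive.
#'
#' @param assay_5b3_percent,assay_1g12_percent percent-of-control activities.
#' @param threshold flagging threshold in percent.
#' @return data.frame with `ratio_percent` and logical `mutant_marker`.
#' @export
compute_binding_ratio <- function(assay_5b3_percent, assay_1g12_percent,
                                  threshold = 150) {
  if (any(!is.finite(assay_5b3_percent)) || any(!is.finite(assay_1g12_percent)) ||
      any(assay_5b3_percent <= 0) || any(assay_1g12_percent <= 0))
    stop("binding-ratio inputs must be positive", call. = FALSE)
  ratio <- assay_5b3_percent / assay_1g12_percent * 100
  data.frame(ratio_percent = ratio, mutant_marker = ratio >= threshold)
}

#' Full phenotype report for a cohort
#'
#' Runs normalization, genotype correction, bin classification and the
#' 5B3/1G12 marker over a phenotype table and a control set.
#'
#' @param samples data.frame with `sample_id`, `id_genotype`, `assay_9b9`,
#'   `assay_1g12`, `assay_5b3` (and optionally `y215c_copies`).
#' @param controls data.frame of control subjects with the same assay columns.
#' @param model a [genotype_model()].
#' @param marker_threshold passed to [compute_binding_ratio()].
#' @return data.frame with `percent`, `corrected_percent`, `bin`,
#'   `binding_ratio_percent`, `mutant_marker`, `corrected` flag.
#' @export
phenotype_report <- function(samples, controls, model = genotype_model(),
                             marker_threshold = 150) {
  for (col in c("assay_9b9", "assay_1g12", "assay_5b3"))
    if (!col %in% names(samples) || !col %in% names(controls))
      stop("missing assay column: ", col, call. = FALSE)
  pct <- normalize_to_control(samples$assay_9b9, controls$assay_9b9)
  corrected_flag <- samples$id_genotype %in% names(model$factors)
  corr <- suppressWarnings(correct_for_genotype(pct, samples$id_genotype, model))
  if (any(!corrected_flag))
    message(sum(!corrected_flag), " sample(s) left uncorrected (unknown genotype)")
  p5b3 <- normalize_to_control(samples$assay_5b3, controls$assay_5b3)
  p1g12 <- normalize_to_control(samples$assay_1g12, controls$assay_1g12)
  br <- compute_binding_ratio(p5b3, p1g12, threshold = marker_threshold)
  data.frame(
    sample_id = samples$sample_id,
    percent = pct,
    corrected_percent = corr,
    bin = classify_bin(corr),
    binding_ratio_percent = br$ratio_percent,
    mutant_marker = br$mutant_marker,
    corrected = corrected_flag,
    stringsAsFactors = FALSE
  )
}
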