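#' Simulation parameters for a synthetic Y215C carrier cohort
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults encode
#' the stated world the downstream analysis assumes: Hardy-Weinberg I/D
#' genotypes at allele frequency `d_allele_freq`, a multiplicative genotype
#' effect on blood ACE level (DD 66% above II), a per-allele expression
#' deficit for the Y215C mutant protein, log-normal multiplicative assay
#' noise, and an elevated 5B3 binding affinity for the mutant molecule.
#'
#' @param n_individuals number of simulated subjects.
#' @param d_allele_freq frequency of the D allele of the ACE I/D
#'   polymorphism, in `[0,1]`. The default 0.5 makes ID the modal genotype.
#' @param genotype_factors named positive multipliers for the II, ID and DD
#'   genotypes. Defaults 1.00/1.33/1.66 reproduce the reported 66% excess of
#'   DD over II blood ACE.
#' @param mutant_allele_expr relative ACE output of one Y215C allele, in
#'   `[0,1]`. The default 0.24 places a noise-free heterozygote at 62% of the
#'   population mean, the cohort median.
#' @param carrier_freq Y215C allele frequency (default 0.015, ~1.5%);
#'   mutant copies are drawn under Hardy-Weinberg, so homozygotes occur at
#'   `carrier_freq^2`.
#' @param assay_cv coefficient of variation of the log-normal measurement
#'   noise (default 0.12). Zero switches noise off.
#' @param mutant_5b3_multiplier relative 5B3 binding of the mutant molecule
#'   (default 4.6, placing a heterozygote 5B3/1G12 ratio at 170%).
#' @param seed integer seed; all draws flow from this single stream.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_individuals = 84L,
                          d_allele_freq = 0.5,
                          genotype_factors = c(II = 1.00, ID = 1.33, DD = 1.66),
                          mutant_allele_expr = 0.24,
                          carrier_freq = 0.015,
                          assay_cv = 0.12,
                          mutant_5b3_multiplier = 4.6,
                          seed = 1L) {
  if (length(n_individuals) != 1L || is.na(n_individuals) || n_individuals < 1)
    stop("n_individuals must be a positive count", call. = FALSE)
  for (f in c(d_allele_freq, mutant_allele_expr, carrier_freq))
    if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
      stop("frequencies and fractions must lie in [0,1]", call. = FALSE)
  if (!all(c("II", "ID", "DD") %in% names(genotype_factors)))
    stop("genotype_factors must name II, ID and DD", call. = FALSE)
  genotype_factors <- genotype_factors[c("II", "ID", "DD")]
  if (any(genotype_factors <= 0) || mutant_5b3_multiplier <= 0)
    stop("all multipliers must be > 0", call. = FALSE)
  if (assay_cv < 0) stop("assay_cv must be >= 0", call. = FALSE)
  structure(list(
    n_individuals = as.integer(n_individuals),
    d_allele_freq = d_allele_freq,
    genotype_factors = genotype_factors,
    mutant_allele_expr = mutant_allele_expr,
    carrier_freq = carrier_freq,
    assay_cv = assay_cv,
    mutant_5b3_multiplier = mutant_5b3_multiplier,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

hwe_weights <- function(q) c(II = (1 - q)^2, ID = 2 * q * (1 - q), DD = q^2)

#' @keywords internal
hwe_mean_factor <- function(config) {
  sum(hwe_weights(config$d_allele_freq) * config$genotype_factors)
}

lnorm_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Draw one log-normal noise vector with unit median
#' @keywords internal
assay_noise <- function(n, cv) {
  if (cv == 0) rep(1, n) else stats::rlnorm(n, meanlog = 0, sdlog = lnorm_sdlog(cv))
}

#' Structural (noise-free) ACE output components, in percent of the
#' population mean. Genotype factor scaled by the HWE mean so that the
#' population expectation is 100.
#' @keywords internal
structural_parts <- function(id_genotype, y215c_copies, config) {
  fbar <- hwe_mean_factor(config)
  g <- 100 * config$genotype_factors[id_genotype] / fbar
  wt <- (2 - y215c_copies) / 2
  mut <- config$mutant_allele_expr * y215c_copies / 2
  list(wt = unname(g * wt), mut = unname(g * mut))
}

#' Generate a synthetic cohort of Y215C carriers and non-carriers
#'
#' I/D genotypes are drawn under Hardy-Weinberg equilibrium, Y215C copies
#' per `carrier_freq`, and the underlying blood ACE level follows a linear
#' allele-dosage model scaled so the population mean is 100:
#' `true_level = 100 * factor(g)/fbar * (wt + expr * mut)/2 * noise`.
#'
#' @param config a [cohort_config()].
#' @return a data.frame (class `ace_cohort`) with columns `sample_id`,
#'   `id_genotype`, `y215c_copies`, `true_level`; assay columns are added by
#'   [generate_assay_panel()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  geno <- sample(c("II", "ID", "DD"), n, replace = TRUE,
                 prob = hwe_weights(config$d_allele_freq))
  copies <- stats::rbinom(n, 2L, config$carrier_freq)
  parts <- structural_parts(geno, copies, config)
  level <- (parts$wt + parts$mut) * assay_noise(n, config$assay_cv)
  out <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    id_genotype = geno,
    y215c_copies = copies,
    true_level = level,
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- config
  class(out) <- c("ace_cohort", "data.frame")
  out
}

#' Attach simulated mAb-precipitated activities to a cohort
#'
#' 9B9 and 1G12 report total ACE (wild-type and mutant molecules weighted
#' equally); 5B3 binds the mutant molecule `mutant_5b3_multiplier` times more
#' strongly. Each assay receives an independent log-normal noise draw; the
#' stream continues from [generate_cohort()], so seeding the config and
#' running both in sequence is fully reproducible.
#'
#' @param individuals an `ace_cohort`.
#' @param config the same [cohort_config()] used to generate it.
#' @return the cohort with `assay_9b9`, `assay_1g12`, `assay_5b3` columns.
#' @export
generate_assay_panel <- function(individuals, config) {
  stopifnot(inherits(individuals, "data.frame"))
  parts <- structural_parts(individuals$id_genotype, individuals$y215c_copies, config)
  n <- nrow(individuals)
  total <- parts$wt + parts$mut
  individuals$assay_9b9 <- total * assay_noise(n, config$assay_cv)
  individuals$assay_1g12 <- total * assay_noise(n, config$assay_cv)
  individuals$assay_5b3 <- (parts$wt + config$mutant_5b3_multiplier * parts$mut) *
    assay_noise(n, config$assay_cv)
  individuals
}

#' Simulate a pQTL summary-statistic table
#'
#' Null variants draw `beta ~ N(0, se)` with the standard-error implied by
#' the allele frequency and sample size, so their two-sided p-values are
#' uniform. Planted effects keep their stated beta and receive the p-value
#' implied by `beta`, `carrier_fraction` and `n_samples` under the same
#' Wald approximation. P-values are floored at the smallest normal double.
#'
#' @param n_null number of null variants.
#' @param planted data.frame with columns `variant_id`, `gene`, `beta`,
#'   `carrier_fraction` (allele fraction in `(0,1)`), or NULL.
#' @param n_samples cohort size behind the summary statistics.
#' @param seed integer seed; also drives the deterministic output shuffle.
#' @return a data.frame (class `summary_stats`) with columns `variant_id`,
#'   `gene`, `consequence`, `beta`, `p_value`, `maf`.
#' @export
generate_pqtl_table <- function(n_null, planted = NULL, n_samples = 35559L, seed = 1L) {
  if (n_null < 0) stop("n_null must be >= 0", call. = FALSE)
  set.seed(seed)
  rows <- list()
  if (n_null > 0) {
    maf <- stats::runif(n_null, 0.01, 0.5)
    se <- 1 / sqrt(2 * n_samples * maf * (1 - maf))
    beta <- stats::rnorm(n_null, 0, se)
    p <- 2 * stats::pnorm(-abs(beta / se))
    cons <- sample(c("missense", "synonymous", "intronic", "other"),
                   n_null, replace = TRUE, prob = c(0.25, 0.25, 0.4, 0.1))
    rows$null <- data.frame(
      variant_id = sprintf("rsN%06d", seq_len(n_null)),
      gene = sprintf("NULLG%04d", sample.int(max(1L, n_null %/% 3L), n_null, replace = TRUE)),
      consequence = cons, beta = beta, p_value = p, maf = maf,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(planted) && nrow(planted) > 0) {
    if (any(planted$carrier_fraction <= 0 | planted$carrier_fraction >= 1))
      stop("carrier_fraction must lie in (0,1)", call. = FALSE)
    af <- planted$carrier_fraction
    se <- 1 / sqrt(2 * n_samples * af * (1 - af))
    lp <- stats::pnorm(-abs(planted$beta / se), log.p = TRUE) + log(2)
    p <- pmax(exp(lp), .Machine$double.xmin)
    rows$planted <- data.frame(
      variant_id = planted$variant_id, gene = planted$gene,
      consequence = "missense", beta = planted$beta, p_value = p,
      maf = pmin(af, 1 - af), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variant_id = character(), gene = character(),
                      consequence = character(), beta = numeric(),
                      p_value = numeric(), maf = numeric())
  }
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Simulate a grouped sample-by-variant genotype matrix
#'
#' Background variants are common (MAF drawn in `[0.05, 0.5]`) and forced to
#' carry at least one carrier in each group, so none is exclusive. Each
#' planted exclusive variant is carried by `k` individuals, `k` uniform in
#' `recurrence_range`, all in the high-ACE group and none in the low group.
#' Missing calls are sprinkled at `missing_rate`.
#'
#' @param n_high,n_low group sizes (high- and low-ACE).
#' @param n_background_variants number of non-exclusive common variants.
#' @param planted_exclusive number of planted exclusive variants.
#' @param recurrence_range integer `c(min, max)` carriers per planted variant.
#' @param missing_rate fraction of calls set missing.
#' @param seed integer seed.
#' @return a [genotype_matrix()] with `group` and `gene_of` filled in.
#' @export
generate_genotype_matrix <- function(n_high, n_low, n_background_variants = 100L,
                                     planted_exclusive = 0L,
                                     recurrence_range = c(3L, 5L),
                                     missing_rate = 0, seed = 1L) {
  if (n_high < 1 || n_low < 1) stop("both groups must be non-empty", call. = FALSE)
  if (recurrence_range[2] > n_high)
    stop("recurrence window exceeds the high-group size", call. = FALSE)
  if (recurrence_range[1] < 1 || recurrence_range[1] > recurrence_range[2])
    stop("invalid recurrence_range", call. = FALSE)
  set.seed(seed)
  n <- n_high + n_low
  samples <- c(sprintf("HI%03d", seq_len(n_high)), sprintf("LO%03d", seq_len(n_low)))
  group <- stats::setNames(rep(c("high", "low"), c(n_high, n_low)), samples)
  high_idx <- seq_len(n_high)
  low_idx <- n_high + seq_len(n_low)

  nv <- n_background_variants + planted_exclusive
  calls <- matrix(0L, nrow = n, ncol = nv,
                  dimnames = list(samples, c(
                    if (n_background_variants > 0) sprintf("bg%05d", seq_len(n_background_variants)),
                    if (planted_exclusive > 0) sprintf("pl%05d", seq_len(planted_exclusive)))))
  if (n_background_variants > 0) {
    maf <- stats::runif(n_background_variants, 0.05, 0.5)
    for (j in seq_len(n_background_variants)) {
      g <- stats::rbinom(n, 2L, maf[j])
      # background variants must not be exclusive: guarantee a carrier per group
      if (all(g[high_idx] == 0L)) g[sample(high_idx, 1L)] <- 1L
      if (all(g[low_idx] == 0L)) g[sample(low_idx, 1L)] <- 1L
      calls[, j] <- g
    }
  }
  if (planted_exclusive > 0) {
    ks <- sample(seq(recurrence_range[1], recurrence_range[2]),
                 planted_exclusive, replace = TRUE)
    for (j in seq_len(planted_exclusive)) {
      who <- sample(high_idx, ks[j])
      # mostly heterozygous carriers, occasional homozygote (counted once)
      calls[who, n_background_variants + j] <-
        sample(c(1L, 2L), ks[j], replace = TRUE, prob = c(0.9, 0.1))
    }
  }
  if (missing_rate > 0) {
    drop <- stats::runif(length(calls)) < missing_rate
    calls[drop] <- NA_integer_
  }
  genes <- stats::setNames(
    c(if (n_background_variants > 0) sprintf("BGGENE%05d", seq_len(n_background_variants)),
      if (planted_exclusive > 0) sprintf("PLGENE%05d", seq_len(planted_exclusive))),
    colnames(calls))
  genotype_matrix(calls, group = group, gene_of = genes)
}
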