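#' Run the full analysis pipeline from a configuration
#'
#' Sequences the stages simulate (optional) -> phenotype -> pqtl-screen ->
#' carrier-screen -> protective-screen, writing every stage's output files
#' under `out_dir` and returning a single run report with input/output
#' counts, the thresholds used, the seed and the package version. Identical
#' configuration and seed give an identical report: nothing in the data
#' files carries a timestamp.
#'
#' @param config a named list (or path to a JSON file) with optional
#'   elements:
#'   \describe{
#'     \item{seed}{integer, used by the simulate stage (default 1).}
#'     \item{out_dir}{output directory (default `tempdir()`).}
#'     \item{simulate}{list of [cohort_config()] overrides plus
#'       `n_controls`, `n_null_variants`, `n_high`, `n_low`,
#'       `n_background_variants`, `planted_exclusive`; when present the
#'       stage writes `phenotypes.tsv`, `controls.tsv`, `summary_stats.tsv`,
#'       `genotypes.vcf`, `groups.tsv` and wires them into later stages.}
#'     \item{phenotype}{list with `phenotypes`, `controls` paths (TSV).}
#'     \item{pqtl}{list with `summary_stats` path and optional threshold
#'       overrides `nominal_p`, `beta_abs_min`, `bonferroni_p`,
#'       `large_beta_abs`.}
#'     \item{carrier}{list with `genotypes` (VCF/TSV path); uses the refined
#'       list from the pqtl stage and bins from the phenotype stage.}
#'     \item{protective}{list with `genotypes`, `groups` paths and optional
#'       `max_missing`, `min_maf`, `window`, `maf_before_exclusive`.}
#'   }
#' @return the run report, invisibly also written to
#'   `file.path(out_dir, "run_report.json")`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% tempdir()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(tool = "acemod",
                 version = as.character(utils::packageVersion("acemod")),
                 seed = seed, stages = list())

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    cc_args <- sim[intersect(names(sim), names(formals(cohort_config)))]
    cc_args$seed <- seed
    cc <- do.call(cohort_config, cc_args)
    cohort <- generate_assay_panel(generate_cohort(cc), cc)
    ctrl_cc <- cc
    ctrl_cc$n_individuals <- as.integer(sim$n_controls %||% 48L)
    ctrl_cc$carrier_freq <- 0
    ctrl_cc$seed <- seed + 1L
    controls <- generate_assay_panel(generate_cohort(ctrl_cc), ctrl_cc)
    stats_tab <- generate_pqtl_table(
      n_null = as.integer(sim$n_null_variants %||% 2000L),
      planted = data.frame(variant_id = "rs3730025", gene = "ACE",
                           beta = -1.217, carrier_fraction = 0.015),
      seed = seed + 2L)
    gm <- generate_genotype_matrix(
      n_high = as.integer(sim$n_high %||% 15L),
      n_low = as.integer(sim$n_low %||% 44L),
      n_background_variants = as.integer(sim$n_background_variants %||% 200L),
      planted_exclusive = as.integer(sim$planted_exclusive %||% 42L),
      missing_rate = sim$missing_rate %||% 0,
      seed = seed + 3L)
    paths <- list(phenotypes = file.path(out_dir, "phenotypes.tsv"),
                  controls = file.path(out_dir, "controls.tsv"),
                  summary_stats = file.path(out_dir, "summary_stats.tsv"),
                  genotypes = file.path(out_dir, "genotypes.vcf"),
                  groups = file.path(out_dir, "groups.tsv"))
    write_tsv(cohort, paths$phenotypes)
    write_tsv(controls, paths$controls)
    write_tsv(stats_tab, paths$summary_stats)
    write_variant_calls(gm, paths$genotypes)
    write_tsv(data.frame(sample_id = rownames(gm$calls), group = gm$group),
              paths$groups)
    config$phenotype <- list(phenotypes = paths$phenotypes, controls = paths$controls)
    config$pqtl <- c(config$pqtl, list(summary_stats = paths$summary_stats))
    config$protective <- c(config$protective,
                           list(genotypes = paths$genotypes, groups = paths$groups))
    report$stages$simulate <- list(
      n_individuals = nrow(cohort), n_controls = nrow(controls),
      n_summary_variants = nrow(stats_tab),
      matrix_dim = dim(gm), planted_exclusive = as.integer(sim$planted_exclusive %||% 42L))
  }

  pheno <- NULL
  if (!is.null(config$phenotype)) {
    ph <- config$phenotype
    samples <- read_phenotypes(ph$phenotypes)
    controls <- read_phenotypes(ph$controls)
    pheno <- phenotype_report(samples, controls)
    write_tsv(pheno, file.path(out_dir, "phenotype_report.tsv"))
    report$stages$phenotype <- list(
      n_samples = nrow(pheno),
      n_uncorrected = sum(!pheno$corrected),
      bins = as.list(table(pheno$bin)),
      n_mutant_marker = sum(pheno$mutant_marker))
  }

  refined <- NULL
  if (!is.null(config$pqtl)) {
    pq <- config$pqtl
    th_args <- pq[intersect(names(pq), names(formals(screen_thresholds)))]
    th <- do.call(screen_thresholds, th_args)
    records <- read_summary_stats(pq$summary_stats)
    cand <- filter_candidates(records, th)
    shortlist <- bonferroni_select(cand, th)
    large <- large_effect_subset(cand, th)
    refined <- cand
    gs <- summarize_genes(shortlist)
    write_tsv(shortlist, file.path(out_dir, "bonferroni_shortlist.tsv"))
    write_tsv(refined, file.path(out_dir, "refined_list.tsv"))
    report$stages$pqtl_screen <- list(
      n_input = nrow(records), n_candidates = nrow(cand),
      n_bonferroni = gs$n_variants, n_genes = gs$n_genes,
      n_cis = gs$n_cis, n_singleton_trans = gs$n_singleton_trans,
      n_large_effect = nrow(large),
      thresholds = th[c("nominal_p", "beta_abs_min", "bonferroni_p", "large_beta_abs")])
  }

  if (!is.null(config$carrier) && !is.null(refined) && !is.null(pheno)) {
    gm <- read_variant_calls(config$carrier$genotypes)
    calls <- carrier_screen(gm, pheno, refined)
    write_tsv(calls, file.path(out_dir, "carrier_calls.tsv"))
    report$stages$carrier_screen <- list(
      n_carriers = nrow(calls),
      calls = as.list(table(calls$call)))
  }

  if (!is.null(config$protective)) {
    pr <- config$protective
    gm <- read_variant_calls(pr$genotypes, group = pr$groups)
    res <- protective_screen(gm,
                             max_missing = pr$max_missing %||% 0.05,
                             min_maf = pr$min_maf %||% 0.05,
                             window = pr$window %||% c(3L, 5L),
                             maf_before_exclusive = isTRUE(pr$maf_before_exclusive))
    write_tsv(res$association, file.path(out_dir, "association.tsv"))
    write_tsv(res$recurrent, file.path(out_dir, "exclusive_recurrent.tsv"))
    report$stages$protective_screen <- list(
      qc = as.list(res$qc_counts),
      lambda_gc = res$lambda_gc,
      n_exclusive = unname(res$counts["n_exclusive"]),
      n_recurrent = unname(res$counts["n_recurrent"]),
      n_genes = unname(res$counts["n_genes"]))
  }

  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
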