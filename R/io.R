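#' Read a genotype matrix from VCF or a dosage TSV
#'
#' VCF v4.2 files (extension `.vcf`) are parsed with
#' `VariantAnnotation::readVcf`; GT fields map losslessly to dosages
#' (`0/0` -> 0, `0/1` or `1/0` -> 1, `1/1` -> 2, `./.` -> missing; phased
#' separators are accepted, and any non-reference allele index counts one
#' dose, so split multi-allelic records behave sensibly). Anything else is
#' read as a tab-separated sample x variant table with `{0,1,2,NA}` dosages,
#' first column `sample_id`. Sample order is preserved.
#'
#' @param path file path.
#' @param group optional named character vector (`"high"`/`"low"`) or path
#'   to a two-column TSV (`sample_id`, `group`).
#' @return a [genotype_matrix()].
#' @export
read_variant_calls <- function(path, group = NULL) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) {
    vcf <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stop("VCF has no GT field: ", path, call. = FALSE)
    calls <- t(apply(gt, c(1, 2), gt_to_dosage))
    if (is.null(dim(calls)))  # single sample edge case
      calls <- matrix(calls, ncol = 1, dimnames = list(names(calls), colnames(gt)))
    info <- VariantAnnotation::info(vcf)
    gene_of <- if ("GENE" %in% names(info))
      stats::setNames(as.character(info$GENE), rownames(gt)) else NULL
  } else {
    tab <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
    if (names(tab)[1] != "sample_id")
      stop("dosage TSV must start with a sample_id column: ", path, call. = FALSE)
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids)) stop("duplicated sample IDs in ", path, call. = FALSE)
    calls <- as.matrix(tab[, -1, with = FALSE])
    rownames(calls) <- ids
    gene_of <- NULL
  }
  if (is.character(group) && length(group) == 1 && file.exists(group)) {
    gtab <- data.table::fread(group, sep = "\t", header = TRUE)
    group <- stats::setNames(as.character(gtab$group), gtab$sample_id)
  }
  genotype_matrix(calls, group = group, gene_of = gene_of)
}

gt_to_dosage <- function(gt) {
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".") || length(alleles) == 0) return(NA_integer_)
  sum(alleles != "0")
}

#' Write a genotype matrix as a minimal GT-only VCF v4.2
#'
#' Variant IDs are kept; positions are synthetic indices on a single
#' placeholder contig (the pipeline keys on variant ID strings, not
#' coordinates). Gene symbols travel in the `GENE` INFO field. The output
#' is deterministic: no timestamps.
#'
#' @param matrix a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_calls <- function(matrix, path) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  calls <- matrix$calls
  gt_str <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(calls)), collapse = "\t")
  )
  genes <- if (is.null(matrix$gene_of)) rep(".", ncol(calls))
           else ifelse(is.na(matrix$gene_of), ".", matrix$gene_of)
  body <- vapply(seq_len(ncol(calls)), function(j) {
    gts <- ifelse(is.na(calls[, j]), "./.", gt_str[calls[, j] + 1L])
    paste(c("1", j, colnames(calls)[j], "A", "G", ".", ".",
            paste0("GENE=", genes[j]), "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a pQTL summary-statistic TSV
#'
#' Expects columns `variant_id`, `gene`, `consequence`, `beta`, `p_value`,
#' `maf` (extra columns pass through). Beta and p tolerate the typeset
#' scientific-notation dialects of the source tables (see
#' [parse_stat_number()]).
#'
#' @param path file path.
#' @return a `summary_stats` data.frame.
#' @export
read_summary_stats <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                         colClasses = list(character = c("beta", "p_value")),
                                         na.strings = "NA"))
  needed <- c("variant_id", "gene", "consequence", "beta", "p_value")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0)
    stop("summary-stat TSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tab$beta <- parse_stat_number(tab$beta)
  tab$p_value <- parse_stat_number(tab$p_value)
  class(tab) <- c("summary_stats", "data.frame")
  tab
}

#' Write a tab-separated table (UTF-8, header, `NA` for missing)
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a phenotype TSV (sample_id, id_genotype, y215c_copies, assays)
#' @param path file path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA"))
}

#' Path to a packaged table fixture
#'
#' Available fixtures: `"table1"` (Y215C carrier frequencies by cohort),
#' `"table2"` (the exome-wide significant Icelandic short list),
#' `"table4"` (the exclusive-variant genotype grid).
#'
#' @param name fixture name.
#' @return file path inside the installed package.
#' @export
acemod_fixture <- function(name = c("table1", "table2", "table4")) {
  name <- match.arg(name)
  fn <- c(table1 = "table1_y215c_frequency.tsv",
          table2 = "table2_icelandic_shortlist.tsv",
          table4 = "table4_exclusive_variants.tsv")[[name]]
  path <- system.file("extdata", fn, package = "acemod")
  if (path == "") stop("fixture not found: ", name, call. = FALSE)
  path
}

#' Parse the exclusive-variant genotype-grid fixture into a genotype matrix
#'
#' The grid has one row per variant with 15 carrier columns holding `-`,
#' `Het` or `Hom`. All 15 subjects belong to the high-ACE group; an empty
#' low group of the given size is appended so the grid can run through the
#' exclusivity and recurrence operations unchanged.
#'
#' @param path path to the grid TSV (default: the packaged fixture).
#' @param n_low size of the all-reference low group to append (default 44).
#' @return a grouped [genotype_matrix()].
#' @export
read_genotype_grid <- function(path = acemod_fixture("table4"), n_low = 44L) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  sample_cols <- setdiff(names(tab), c("row", "gene", "cdna", "variant_id",
                                       "maf_gnomad_100k", "maf_fmba_100k"))
  code <- function(x) c("-" = 0L, "Het" = 1L, "Hom" = 2L)[x]
  calls <- t(vapply(seq_len(nrow(tab)),
                    function(i) code(unlist(tab[i, sample_cols])),
                    integer(length(sample_cols))))
  calls <- t(calls)  # samples x variants
  rownames(calls) <- sample_cols
  colnames(calls) <- tab$variant_id
  if (n_low > 0) {
    lows <- matrix(0L, nrow = n_low, ncol = ncol(calls),
                   dimnames = list(sprintf("LOW%03d", seq_len(n_low)), colnames(calls)))
    calls <- rbind(calls, lows)
  }
  group <- stats::setNames(rep(c("high", "low"), c(length(sample_cols), n_low)),
                           rownames(calls))
  genotype_matrix(calls, group = group,
                  gene_of = stats::setNames(tab$gene, tab$variant_id))
}
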