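#' Export a simulated dataset as VCF + TSV
#'
#' Writes `genotypes.vcf` (VCFv4.2, GT field only; dosage 0 -> `0/0`,
#' 1 -> `0/1`, 2 -> `1/1`, missing -> `./.`), `cohort.tsv` and `panel.tsv`
#' under `path`. The cohort schema is fixed:
#' `iid sex birth_year death_year lifespan age chip subpop` (plus a trailing
#' `offspring_iid` column when parent-offspring links exist). Numeric columns
#' are written with 17 significant digits so that [read_dataset()]
#' round-trips dosages and phenotype values bit-exactly.
#'
#' @param genotypes Individuals x variants dosage matrix.
#' @param panel A `variant_panel`.
#' @param cohort A `cohort_table` with rows matching `genotypes`.
#' @param path Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
export_dataset <- function(genotypes, panel, cohort, path) {
  if (nrow(genotypes) != nrow(cohort) || ncol(genotypes) != nrow(panel)) {
    stop("genotype, panel and cohort dimensions are inconsistent", call. = FALSE)
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)

  vcf_path <- file.path(path, "genotypes.vcf")
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(genotypes), ncol(genotypes))
  ok <- !is.na(genotypes)
  gt[ok] <- gt_codes[genotypes[ok] + 1L]

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=proxygwas",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$iid), collapse = "\t")
  )
  body <- paste(panel$chrom, format(panel$pos, scientific = FALSE, trim = TRUE),
                panel$variant, panel$ref, panel$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)

  cohort_path <- file.path(path, "cohort.tsv")
  tab <- data.frame(
    iid = cohort$iid,
    sex = cohort$sex,
    birth_year = cohort$birth_year,
    death_year = num17(cohort$death_year),
    lifespan = num17(cohort$lifespan),
    age = cohort$age_at_snapshot,
    chip = cohort$chip,
    subpop = cohort$subpop,
    stringsAsFactors = FALSE
  )
  if (!is.null(cohort$offspring_iid)) tab$offspring_iid <- cohort$offspring_iid
  utils::write.table(tab, cohort_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")

  panel_path <- file.path(path, "panel.tsv")
  ptab <- panel
  ptab$freq <- num17(panel$freq)
  beta_cols <- grep("^beta_", names(ptab))
  for (j in beta_cols) ptab[[j]] <- num17(panel[[names(ptab)[j]]])
  utils::write.table(ptab, panel_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")

  invisible(c(vcf = vcf_path, cohort = cohort_path, panel = panel_path))
}

num17 <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))

#' Read back a dataset written by [export_dataset()]
#'
#' The VCF is parsed with \pkg{vcfR}; GT strings are decoded back to dosages
#' (`./.` -> NA). Dosage and phenotype values round-trip bit-exactly.
#'
#' @param path Directory previously passed to [export_dataset()].
#' @return A list with `genotypes`, `panel`, `cohort`.
#' @export
read_dataset <- function(path) {
  vcf <- vcfR::read.vcfR(file.path(path, "genotypes.vcf"), verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos <- t(matrix(unname(code[as.vector(gt)]), nrow(gt), ncol(gt)))
  rownames(dos) <- colnames(gt)
  colnames(dos) <- rownames(gt)

  cohort <- utils::read.delim(file.path(path, "cohort.tsv"),
                              stringsAsFactors = FALSE)
  names(cohort)[names(cohort) == "age"] <- "age_at_snapshot"
  class(cohort) <- c("cohort_table", "data.frame")

  panel <- utils::read.delim(file.path(path, "panel.tsv"),
                             stringsAsFactors = FALSE)
  class(panel) <- c("variant_panel", "data.frame")

  if (!identical(cohort$iid, rownames(dos)) &&
      all(cohort$iid %in% rownames(dos))) {
    dos <- dos[cohort$iid, , drop = FALSE]
  }
  if (nrow(dos) != nrow(cohort)) {
    stop("cohort/genotype sample mismatch on read-back", call. = FALSE)
  }
  list(genotypes = dos, panel = panel, cohort = cohort)
}
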