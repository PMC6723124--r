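#' Read a GWAS summary-statistic table
#'
#' Fixed TSV schema `variant chr pos ea oa z n eaf`; with `beta_se = TRUE`
#' the columns `beta` and `se` replace `z` and are converted to
#' `z = beta / se` on read. Alleles must be single bases A/C/G/T, sample
#' sizes positive and frequencies strictly inside (0, 1).
#'
#' @param path TSV file.
#' @param beta_se Input carries `beta`/`se` instead of `z`.
#' @return A `study_summary` data.frame.
#' @export
read_sumstats <- function(path, beta_se = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (beta_se) {
    stopifnot(all(c("beta", "se") %in% names(tab)))
    tab$z <- tab$beta / tab$se
  }
  as_study_summary(tab)
}

#' Validate a summary-statistic table
#'
#' @param tab data.frame with columns `variant`, `chr`, `pos`, `ea`, `oa`,
#'   `z`, `n`, `eaf`.
#' @return The table with class `study_summary`.
#' @export
as_study_summary <- function(tab) {
  need <- c("variant", "chr", "pos", "ea", "oa", "z", "n", "eaf")
  if (!all(need %in% names(tab))) {
    stop("summary statistics need columns: ", paste(need, collapse = " "),
         call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  if (!all(tab$ea %in% bases & tab$oa %in% bases)) {
    stop("alleles must be single bases A/C/G/T", call. = FALSE)
  }
  if (any(tab$n <= 0)) stop("sample sizes must be positive", call. = FALSE)
  if (any(tab$eaf <= 0 | tab$eaf >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  class(tab) <- c("study_summary", "data.frame")
  tab
}

is_ambiguous <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize two summary-statistic sets for meta-analysis
#'
#' Intersects the two studies on variant id and enforces matching alleles:
#' identical effect/other alleles are kept as-is; swapped alleles flip the
#' sign of study b's z (and reorient its frequency); any other combination
#' is dropped. Strand-ambiguous pairs (A/T, C/G) are dropped when the
#' frequency comparison is inconclusive, i.e. when study b's frequency sits
#' closer to the flip of study a's than to study a's itself. Variants with
#' folded MAF below `maf_min` in either study are removed.
#'
#' @param a,b `study_summary` tables.
#' @param maf_min Cohort-specific MAF floor (default 0.005, inclusive).
#' @return A `paired_summary` data.frame with per-study z, n, eaf columns.
#' @export
harmonize_studies <- function(a, b, maf_min = 0.005) {
  for (s in list(a, b)) {
    if (anyDuplicated(s$variant)) {
      stop("duplicate variant ids within a study", call. = FALSE)
    }
  }
  mg <- merge(as.data.frame(a), as.data.frame(b), by = "variant",
              suffixes = c("_a", "_b"))
  if (!nrow(mg)) {
    return(structure(mg, class = c("paired_summary", "data.frame")))
  }

  same <- mg$ea_a == mg$ea_b & mg$oa_a == mg$oa_b
  swap <- mg$ea_a == mg$oa_b & mg$oa_a == mg$ea_b
  mg$z_b[swap] <- -mg$z_b[swap]
  mg$eaf_b[swap] <- 1 - mg$eaf_b[swap]
  keep <- same | swap

  amb <- is_ambiguous(mg$ea_a, mg$oa_a)
  inconclusive <- abs(mg$eaf_a - (1 - mg$eaf_b)) < abs(mg$eaf_a - mg$eaf_b)
  keep <- keep & !(amb & inconclusive)

  maf_a <- pmin(mg$eaf_a, 1 - mg$eaf_a)
  maf_b <- pmin(mg$eaf_b, 1 - mg$eaf_b)
  keep <- keep & maf_a >= maf_min & maf_b >= maf_min

  out <- mg[keep, c("variant", "chr_a", "pos_a", "ea_a", "oa_a",
                    "z_a", "n_a", "eaf_a", "z_b", "n_b", "eaf_b")]
  names(out)[2:5] <- c("chr", "pos", "ea", "oa")
  rownames(out) <- NULL
  class(out) <- c("paired_summary", "data.frame")
  out
}

#' Sample-size-weighted z-score meta-analysis
#'
#' The METAL-style scheme: each study's z is first deflated by the square
#' root of its genomic inflation factor (floored at 1), then combined as
#' `z_meta = (w_a z_a + w_b z_b) / sqrt(w_a^2 + w_b^2)` with weights
#' `w = sqrt(N)`. Two-sided P values follow, with genome-wide significance
#' declared at `alpha` (default 5.0e-8).
#'
#' @param paired A `paired_summary` from [harmonize_studies()].
#' @param lambda_a,lambda_b Per-study genomic inflation factors.
#' @param alpha Significance threshold.
#' @return A `meta_result` data.frame: `variant`, `z_a`, `z_b`, `n_a`,
#'   `n_b`, `z_meta`, `p`, `direction`, `significant`.
#' @export
stouffer_meta <- function(paired, lambda_a = 1, lambda_b = 1, alpha = 5e-8) {
  if (any(paired$n_a <= 0) || any(paired$n_b <= 0)) {
    stop("sample sizes must be positive", call. = FALSE)
  }
  za <- paired$z_a / sqrt(max(lambda_a, 1))
  zb <- paired$z_b / sqrt(max(lambda_b, 1))
  wa <- sqrt(paired$n_a)
  wb <- sqrt(paired$n_b)
  zm <- (wa * za + wb * zb) / sqrt(wa^2 + wb^2)
  dirchar <- function(z) ifelse(z > 0, "+", ifelse(z < 0, "-", "0"))
  out <- data.frame(
    variant = paired$variant,
    z_a = za, z_b = zb, n_a = paired$n_a, n_b = paired$n_b,
    z_meta = zm,
    p = 2 * stats::pnorm(-abs(zm)),
    direction = paste0(dirchar(za), dirchar(zb)),
    significant = 2 * stats::pnorm(-abs(zm)) < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("meta_result", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "lambda") <- c(a = lambda_a, b = lambda_b)
  out
}

#' @export
print.meta_result <- function(x, ..., top = 6L) {
  cat(sprintf("Sample-size-weighted meta-analysis: %d shared variants, %d significant at %g\n",
              nrow(x), sum(x$significant), attr(x, "alpha")))
  ord <- order(x$p)
  print.data.frame(utils::head(x[ord, ], top), digits = 4, row.names = FALSE)
  invisible(x)
}
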