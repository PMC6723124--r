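#' Per-variant quality-control statistics
#'
#' @param genotypes Dosage matrix with possible NAs.
#' @return data.frame with `variant`, `maf` (folded), `missingness`,
#'   `hwe_chi2` (goodness-of-fit of observed genotype counts against the
#'   p^2, 2pq, q^2 expectation at the estimated frequency).
#' @export
variant_stats <- function(genotypes) {
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- sprintf("v%05d", seq_len(ncol(genotypes)))
  n_obs <- colSums(!is.na(genotypes))
  phat <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(phat, 1 - phat)
  miss <- 1 - n_obs / nrow(genotypes)

  n0 <- colSums(genotypes == 0L, na.rm = TRUE)
  n1 <- colSums(genotypes == 1L, na.rm = TRUE)
  n2 <- colSums(genotypes == 2L, na.rm = TRUE)
  e0 <- n_obs * (1 - phat)^2
  e1 <- n_obs * 2 * phat * (1 - phat)
  e2 <- n_obs * phat^2
  term <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
  hwe <- term(n0, e0) + term(n1, e1) + term(n2, e2)

  data.frame(variant = ids, maf = maf, missingness = miss, hwe_chi2 = hwe,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Variant quality control: missingness, MAF and worst-HWE filters
#'
#' Filters are applied in a fixed order: (1) drop variants with missingness
#' above `var_missing_max`; (2) drop variants with folded minor-allele
#' frequency below `maf_min` (the thresholds are inclusive: MAF exactly at
#' `maf_min`, or missingness exactly at `var_missing_max`, is kept); (3)
#' among the survivors, remove the `ceiling(hwe_worst_frac * m)` variants
#' with the largest Hardy-Weinberg chi-square deviation, ties broken by
#' variant id. Defaults mirror common array-QC practice: MAF >= 0.5%,
#' variant missingness <= 20%, worst 1% of HWE deviations removed.
#'
#' @param genotypes Dosage matrix (individuals x variants).
#' @param maf_min Minimum folded MAF (inclusive).
#' @param var_missing_max Maximum variant missingness (inclusive).
#' @param hwe_worst_frac Fraction of surviving variants to remove by HWE rank.
#' @return A `qc_report`: list with `kept` (surviving variant ids), `removed`
#'   (named list of ids per filter), `stats` (per-variant statistics) and
#'   `counts`.
#' @export
variant_qc <- function(genotypes, maf_min = 0.005, var_missing_max = 0.20,
                       hwe_worst_frac = 0.01) {
  if (ncol(genotypes) == 0L || nrow(genotypes) == 0L) {
    stop("empty genotype matrix", call. = FALSE)
  }
  st <- variant_stats(genotypes)

  rm_miss <- st$variant[st$missingness > var_missing_max]
  left <- st[!(st$variant %in% rm_miss), , drop = FALSE]
  rm_maf <- left$variant[left$maf < maf_min]
  left <- left[!(left$variant %in% rm_maf), , drop = FALSE]

  rm_hwe <- character(0)
  if (hwe_worst_frac > 0 && nrow(left) > 0L) {
    k <- min(ceiling(hwe_worst_frac * nrow(left)), nrow(left))
    ord <- order(-left$hwe_chi2, left$variant)
    rm_hwe <- left$variant[ord[seq_len(k)]]
    left <- left[!(left$variant %in% rm_hwe), , drop = FALSE]
  }
  if (nrow(left) == 0L) stop("all variants removed by QC", call. = FALSE)

  report <- list(
    kept = left$variant,
    removed = list(missingness = rm_miss, maf = rm_maf, hwe = rm_hwe),
    stats = st,
    counts = c(input = nrow(st),
               removed_missingness = length(rm_miss),
               removed_maf = length(rm_maf),
               removed_hwe = length(rm_hwe),
               kept = nrow(left))
  )
  class(report) <- "qc_report"
  report
}

#' Individual quality control by genotype missingness
#'
#' Removes individuals whose fraction of missing genotype calls exceeds
#' `ind_missing_max` (default 2%, exclusive: exactly at the threshold is
#' kept).
#'
#' @param genotypes Dosage matrix.
#' @param ind_missing_max Maximum per-individual missingness.
#' @return A `qc_report` with `kept`/`removed` individual ids and per-row
#'   missingness in `stats`.
#' @export
individual_qc <- function(genotypes, ind_missing_max = 0.02) {
  if (nrow(genotypes) == 0L) stop("empty genotype matrix", call. = FALSE)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- sprintf("i%05d", seq_len(nrow(genotypes)))
  miss <- rowMeans(is.na(genotypes))
  removed <- ids[miss > ind_missing_max]
  kept <- setdiff(ids, removed)
  if (length(kept) == 0L) stop("all individuals removed by QC", call. = FALSE)
  report <- list(
    kept = kept,
    removed = list(missingness = removed),
    stats = data.frame(iid = ids, missingness = miss,
                       stringsAsFactors = FALSE, row.names = NULL),
    counts = c(input = length(ids), removed_missingness = length(removed),
               kept = length(kept))
  )
  class(report) <- "qc_report"
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  for (nm in names(x$counts)) cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Write a QC report as TSV + JSON summary
#'
#' @param report A `qc_report`.
#' @param path Output directory.
#' @return Invisibly the file paths.
#' @export
write_qc_report <- function(report, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(path, "qc_stats.tsv")
  utils::write.table(report$stats, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(path, "qc_summary.json")
  jsonlite::write_json(list(counts = as.list(report$counts),
                            removed = report$removed),
                       js, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(tsv = tsv, json = js))
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `window` variants advancing by `step`; within each
#' window, while any remaining pair has squared correlation above `r2_max`,
#' the pair with the largest r^2 is processed first (ties by lowest column
#' index pair) and the member with the lower minor-allele frequency is
#' removed (on an exact MAF tie, the higher column index). Because removal
#' only ever shrinks the set, a single left-to-right pass leaves no
#' surviving within-window pair above the threshold.
#'
#' @param genotypes Dosage matrix.
#' @param panel Optional `variant_panel` (used only for variant ids when the
#'   matrix has no column names).
#' @param r2_max Maximum tolerated squared correlation (default 0.9).
#' @param window Window width in variants.
#' @param step Window step in variants.
#' @return Character vector of surviving variant ids, in panel order.
#' @export
ld_prune <- function(genotypes, panel = NULL, r2_max = 0.9,
                     window = 50L, step = 5L) {
  m <- ncol(genotypes)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- if (!is.null(panel)) panel$variant else
    sprintf("v%05d", seq_len(m))
  if (m <= 1L) return(ids)
  phat <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(phat, 1 - phat)
  keep <- rep(TRUE, m)

  starts <- seq(1L, max(1L, m - 1L), by = step)
  for (s in starts) {
    w <- s:min(s + window - 1L, m)
    repeat {
      idx <- w[keep[w]]
      if (length(idx) < 2L) break
      cc <- suppressWarnings(
        stats::cor(genotypes[, idx, drop = FALSE],
                   use = "pairwise.complete.obs"))
      cc[!is.finite(cc)] <- 0
      r2 <- cc^2
      diag(r2) <- 0
      if (max(r2) <= r2_max) break
      hit <- which(r2 == max(r2), arr.ind = TRUE)
      hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
      a <- idx[hit[1, 1]]; b <- idx[hit[1, 2]]
      drop <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else max(a, b)
      keep[drop] <- FALSE
    }
  }
  ids[keep]
}

#' Principal-component covariates from a near-independent SNP subset
#'
#' Follows array-GWAS practice: prune the panel to approximate linkage
#' equilibrium (r^2 < `ld_r2`), sample `n_snps_subset` of the survivors,
#' standardize each SNP by its estimated binomial scale
#' \eqn{\sqrt{2\hat p(1-\hat p)}} (missing entries are mean-imputed after
#' centering), and take the top `k` components of the exact singular value
#' decomposition. Constant SNP columns are dropped with a warning.
#'
#' @param genotypes Dosage matrix.
#' @param n_snps_subset Number of SNPs to sample after LD pruning.
#' @param k Number of components (default 10).
#' @param seed Seed for the SNP subsample.
#' @param ld_r2 r^2 ceiling for the pruning pass (default 0.2).
#' @param window,step Pruning window parameters.
#' @return A `pc_result`: list with `scores` (n x k), `explained`
#'   (non-increasing variance shares) and `snps` used.
#' @export
pca_covariates <- function(genotypes, n_snps_subset = ncol(genotypes),
                           k = 10L, seed = 1L, ld_r2 = 0.2,
                           window = 50L, step = 5L) {
  kept <- ld_prune(genotypes, r2_max = ld_r2, window = window, step = step)
  ids <- colnames(genotypes)
  if (is.null(ids)) {
    ids <- sprintf("v%05d", seq_len(ncol(genotypes)))
    colnames(genotypes) <- ids
  }
  set.seed(seed)
  use <- if (length(kept) > n_snps_subset) {
    sort(sample(kept, n_snps_subset))
  } else kept
  g <- genotypes[, use, drop = FALSE]

  phat <- colMeans(g, na.rm = TRUE) / 2
  keepcol <- phat > 0 & phat < 1
  if (!all(keepcol)) {
    warning(sum(!keepcol), " constant SNP column(s) dropped before PCA")
    g <- g[, keepcol, drop = FALSE]
    phat <- phat[keepcol]
    use <- use[keepcol]
  }
  x <- sweep(g, 2L, 2 * phat)
  x[is.na(x)] <- 0
  x <- sweep(x, 2L, sqrt(2 * phat * (1 - phat)), "/")

  sv <- svd(x)
  rank <- sum(sv$d > max(dim(x)) * .Machine$double.eps * sv$d[1])
  if (k > rank) stop("k exceeds the rank of the standardized genotype matrix",
                     call. = FALSE)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(genotypes)
  colnames(scores) <- paste0("PC", seq_len(k))
  res <- list(scores = scores,
              explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
              snps = use)
  class(res) <- "pc_result"
  res
}

#' @export
print.pc_result <- function(x, ...) {
  cat(sprintf("PCA covariates: %d individuals x %d components (%d SNPs)\n",
              nrow(x$scores), ncol(x$scores), length(x$snps)))
  cat("  explained variance:",
      paste(sprintf("%.3f", x$explained), collapse = " "), "\n")
  invisible(x)
}

#' Prune samples until no pair is more related than a cM threshold
#'
#' Repeatedly takes the most-related pair still above `threshold` and drops
#' one of its two members uniformly at random (seeded), until no kept pair
#' exceeds the threshold. Default 300 cM, below the sharing of any close
#' relative pair. An individual that appears in no above-threshold pair is
#' never removed.
#'
#' @param relatedness data.frame `id1`, `id2`, `cm` (symmetric scores; each
#'   unordered pair listed once).
#' @param threshold Maximum tolerated pairwise sharing in cM.
#' @param seed Seed for the random member choice.
#' @return Character vector of kept individual ids.
#' @export
prune_relatives <- function(relatedness, threshold = 300, seed = 1L) {
  stopifnot(all(c("id1", "id2", "cm") %in% names(relatedness)))
  set.seed(seed)
  ids <- sort(unique(c(relatedness$id1, relatedness$id2)))
  kept <- rep(TRUE, length(ids))
  names(kept) <- ids
  bad <- relatedness[relatedness$cm > threshold, , drop = FALSE]
  bad <- bad[order(-bad$cm, bad$id1, bad$id2), , drop = FALSE]
  repeat {
    live <- kept[bad$id1] & kept[bad$id2]
    if (!any(live)) break
    pair <- bad[which(live)[1L], ]
    victim <- if (stats::runif(1) < 0.5) pair$id1 else pair$id2
    kept[victim] <- FALSE
  }
  names(kept)[kept]
}
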