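#' LD scores in genetic-distance windows
#'
#' The LD score of variant j is the sum of adjusted squared correlations
#' with every variant (itself included) within `window_cm` centimorgans on
#' the same chromosome: `r2_adj = r2 - (1 - r2) / (n_ref - 2)`, the standard
#' small-sample bias correction. Windows default to +/- 1 cM.
#'
#' @param genotypes Reference dosage matrix used to estimate correlations.
#' @param panel `variant_panel` providing `chrom` and `cm` positions.
#' @param window_cm Half-width of the genetic window in cM (default 1.0).
#' @param n_ref Reference sample size for the bias adjustment; defaults to
#'   `nrow(genotypes)`. Must exceed 2.
#' @param adjust Apply the bias correction (set FALSE to get raw-r2 scores
#'   for cross-checks).
#' @return An `ld_score_table` data.frame: `variant`, `chrom`, `cm`, `ell`.
#' @export
compute_ld_scores <- function(genotypes, panel, window_cm = 1.0,
                              n_ref = nrow(genotypes), adjust = TRUE) {
  if (n_ref <= 2) stop("n_ref must exceed 2", call. = FALSE)
  m <- nrow(panel)
  ell <- numeric(m)
  for (cc in unique(panel$chrom)) {
    idx <- which(panel$chrom == cc)
    cm <- panel$cm[idx]
    ord <- order(cm)
    idx <- idx[ord]; cm <- cm[ord]
    g <- genotypes[, idx, drop = FALSE]
    for (a in seq_along(idx)) {
      nb <- which(abs(cm - cm[a]) <= window_cm)
      r <- suppressWarnings(
        stats::cor(g[, a], g[, nb, drop = FALSE],
                   use = "pairwise.complete.obs"))
      r2 <- as.vector(r)^2
      r2[!is.finite(r2)] <- 0
      r2[nb == a] <- 1  # self term is exact
      if (adjust) r2 <- r2 - (1 - r2) / (n_ref - 2)
      ell[idx[a]] <- sum(r2)
    }
  }
  out <- data.frame(variant = panel$variant, chrom = panel$chrom,
                    cm = panel$cm, ell = ell,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ld_score_table", "data.frame")
  out
}

weighted_ls <- function(x, y, w, intercept_fixed = NULL) {
  if (is.null(intercept_fixed)) {
    X <- cbind(1, x)
    wx <- X * w
    cf <- solve(crossprod(wx, X), crossprod(wx, y))
    c(intercept = cf[1], slope = cf[2])
  } else {
    yy <- y - intercept_fixed
    c(intercept = intercept_fixed,
      slope = sum(w * x * yy) / sum(w * x^2))
  }
}

block_jackknife <- function(m, n_blocks, statistic) {
  n_blocks <- max(2L, min(n_blocks, m))
  bounds <- floor(seq(0, m, length.out = n_blocks + 1L))
  est <- vapply(seq_len(n_blocks), function(b) {
    drop_idx <- (bounds[b] + 1L):bounds[b + 1L]
    statistic(setdiff(seq_len(m), drop_idx))
  }, numeric(1))
  est <- est[is.finite(est)]
  nb <- length(est)
  if (nb < 2L) return(NA_real_)
  sqrt((nb - 1) / nb * sum((est - mean(est))^2))
}

#' SNP heritability by LD-score regression
#'
#' Weighted regression of per-variant chi-square statistics on
#' `N * ell / M`; the slope estimates the observed-scale SNP heritability
#' and the intercept (free, or fixed at 1 when `constrain_intercept`) tracks
#' confounding. Weights are `1 / max(ell, 1)`, a deliberate simplification
#' of the full heteroskedasticity weighting. Standard errors come from a
#' delete-a-block jackknife over `n_blocks` contiguous variant blocks.
#'
#' Parental-dose rescaling (a factor of 4 on h2 for offspring-genotype
#' scans) is applied downstream via [rescale_parental()] conventions, never
#' here.
#'
#' @param chi2 Per-variant chi-square statistics (z^2).
#' @param ldscores `ld_score_table` or numeric vector of LD scores, aligned
#'   with `chi2`.
#' @param N GWAS sample size.
#' @param M Number of variants the heritability is spread over (defaults to
#'   `length(chi2)`).
#' @param constrain_intercept Fix the intercept at 1.
#' @param n_blocks Jackknife blocks (default 200).
#' @return An `h2_estimate`: list with `h2`, `se`, `intercept`,
#'   `intercept_se`, `mean_chi2`, `ratio` ((intercept - 1)/(mean chi2 - 1)),
#'   `n_blocks`.
#' @export
estimate_h2 <- function(chi2, ldscores, N, M = length(chi2),
                        constrain_intercept = FALSE, n_blocks = 200L) {
  ell <- if (is.data.frame(ldscores)) ldscores$ell else as.numeric(ldscores)
  stopifnot(length(ell) == length(chi2))
  if (stats::var(ell) < 1e-12) {
    stop("LD scores have zero variance; slope unidentifiable", call. = FALSE)
  }
  x <- N * ell / M
  w <- 1 / pmax(ell, 1)
  fix <- if (constrain_intercept) 1 else NULL
  fit_fun <- function(idx) {
    weighted_ls(x[idx], chi2[idx], w[idx], intercept_fixed = fix)[["slope"]]
  }
  icpt_fun <- function(idx) {
    weighted_ls(x[idx], chi2[idx], w[idx], intercept_fixed = fix)[["intercept"]]
  }
  full <- weighted_ls(x, chi2, w, intercept_fixed = fix)
  se <- block_jackknife(length(chi2), n_blocks, fit_fun)
  intercept_se <- if (constrain_intercept) 0 else
    block_jackknife(length(chi2), n_blocks, icpt_fun)
  mean_chi2 <- mean(chi2)
  out <- list(h2 = unname(full[["slope"]]),
              se = se,
              intercept = unname(full[["intercept"]]),
              intercept_se = intercept_se,
              mean_chi2 = mean_chi2,
              ratio = if (mean_chi2 > 1) (full[["intercept"]] - 1) / (mean_chi2 - 1)
                      else NA_real_,
              n_blocks = n_blocks,
              constrained = constrain_intercept)
  class(out) <- "h2_estimate"
  out
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("LD-score regression h2 = %.4f (SE %.4f)\n", x$h2, x$se))
  cat(sprintf("  intercept = %.4f%s, mean chi2 = %.4f\n", x$intercept,
              if (x$constrained) " (constrained)" else "", x$mean_chi2))
  invisible(x)
}

#' Cross-trait genetic correlation by LD-score regression
#'
#' Regresses the per-variant z-score product on `sqrt(N1 N2) * ell / M`; the
#' slope is the genetic covariance, normalized by the geometric mean of the
#' two SNP heritabilities to give r_g. With `constrain = TRUE` the per-trait
#' heritability intercepts are fixed at 1 and the covariance intercept at
#' `r_p * N12 / sqrt(N1 * N2)`, the expected contribution of phenotypic
#' correlation among overlapping samples; otherwise both are free. Estimates
#' are reported raw -- |r_g| > 1.25 triggers a warning, never truncation.
#'
#' @param z1,z2 Aligned per-variant z-scores of the two traits.
#' @param ldscores LD scores aligned with the z-scores.
#' @param N1,N2 Per-study sample sizes.
#' @param N12 Sample overlap count.
#' @param r_p Phenotypic correlation among overlapping samples.
#' @param constrain Constrain the intercepts as above.
#' @param M Effective variant count (defaults to `length(z1)`).
#' @param n_blocks Jackknife blocks for the r_g standard error.
#' @return An `rg_estimate`: list with `rg`, `se`, `gencov`,
#'   `cov_intercept`, `h2_1`, `h2_2` (each an `h2_estimate`).
#' @export
estimate_rg <- function(z1, z2, ldscores, N1, N2, N12 = 0, r_p = 0,
                        constrain = FALSE, M = length(z1),
                        n_blocks = 200L) {
  ell <- if (is.data.frame(ldscores)) ldscores$ell else as.numeric(ldscores)
  stopifnot(length(z1) == length(z2), length(ell) == length(z1))
  h1 <- estimate_h2(z1^2, ell, N1, M, constrain_intercept = constrain,
                    n_blocks = n_blocks)
  h2 <- estimate_h2(z2^2, ell, N2, M, constrain_intercept = constrain,
                    n_blocks = n_blocks)

  x <- sqrt(N1 * N2) * ell / M
  y <- z1 * z2
  w <- 1 / pmax(ell, 1)
  cov_icpt <- r_p * N12 / sqrt(N1 * N2)
  fix <- if (constrain) cov_icpt else NULL
  cfit <- weighted_ls(x, y, w, intercept_fixed = fix)
  gencov <- unname(cfit[["slope"]])

  flagged <- h1$h2 <= 0 || h2$h2 <= 0
  rg <- if (flagged) NA_real_ else gencov / sqrt(h1$h2 * h2$h2)
  if (!flagged && abs(rg) > 1.25) {
    warning(sprintf("|r_g| = %.3f exceeds 1.25; reported unmodified", abs(rg)))
  }

  rg_fun <- function(idx) {
    s1 <- weighted_ls(N1 * ell[idx] / M, z1[idx]^2, w[idx],
                      intercept_fixed = if (constrain) 1 else NULL)[["slope"]]
    s2 <- weighted_ls(N2 * ell[idx] / M, z2[idx]^2, w[idx],
                      intercept_fixed = if (constrain) 1 else NULL)[["slope"]]
    sc <- weighted_ls(x[idx], y[idx], w[idx], intercept_fixed = fix)[["slope"]]
    if (s1 <= 0 || s2 <= 0) return(NA_real_)
    sc / sqrt(s1 * s2)
  }
  se <- if (flagged) NA_real_ else block_jackknife(length(z1), n_blocks, rg_fun)

  out <- list(rg = rg, se = se, gencov = gencov,
              cov_intercept = unname(cfit[["intercept"]]),
              h2_1 = h1, h2_2 = h2,
              constrained = constrain, flagged = flagged)
  class(out) <- "rg_estimate"
  out
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("Genetic correlation r_g = %.4f (SE %.4f)%s\n", x$rg, x$se,
              if (x$flagged) " [h2 <= 0: undefined]" else ""))
  cat(sprintf("  genetic covariance slope = %.5f, covariance intercept = %.4f%s\n",
              x$gencov, x$cov_intercept,
              if (x$constrained) " (constrained)" else ""))
  cat(sprintf("  h2 trait 1 = %.4f, trait 2 = %.4f\n", x$h2_1$h2, x$h2_2$h2))
  invisible(x)
}

#' Simulate GWAS summary statistics under the LD-score model
#'
#' Draws z-scores with `z_j ~ Normal(0, 1 + N h2 ell_j / M)` for one trait,
#' or a bivariate normal per variant with cross-covariance
#' `rg sqrt(h2_1 h2_2) sqrt(N1 N2) ell_j / M + r_p N12 / sqrt(N1 N2)` for
#' two traits; this is the generative model LD-score regression fits, and
#' serves as the recovery ground truth for [estimate_h2()] and
#' [estimate_rg()].
#'
#' @param ell LD-score vector.
#' @param N1,N2 Sample sizes (`N2 = NULL` for the univariate case).
#' @param h2_1,h2_2 Generating heritabilities.
#' @param rg Generating genetic correlation.
#' @param N12,r_p Sample overlap and phenotypic correlation.
#' @param M Variant count (defaults to `length(ell)`).
#' @param seed Integer seed.
#' @return For one trait, a numeric z vector; for two, a list `z1`, `z2`.
#' @export
simulate_sumstats <- function(ell, N1, h2_1, N2 = NULL, h2_2 = NULL,
                              rg = 0, N12 = 0, r_p = 0, M = length(ell),
                              seed = 1L) {
  set.seed(seed)
  v1 <- 1 + N1 * h2_1 * ell / M
  if (is.null(N2)) {
    return(stats::rnorm(length(ell), 0, sqrt(v1)))
  }
  v2 <- 1 + N2 * h2_2 * ell / M
  cv <- rg * sqrt(h2_1 * h2_2) * sqrt(N1 * N2) * ell / M +
    r_p * N12 / sqrt(N1 * N2)
  # per-variant 2x2 Cholesky, vectorized
  a <- sqrt(v1)
  b <- cv / a
  c2 <- pmax(v2 - b^2, 1e-12)
  e1 <- stats::rnorm(length(ell))
  e2 <- stats::rnorm(length(ell))
  list(z1 = a * e1, z2 = b * e1 + sqrt(c2) * e2)
}

#' Write LD scores as TSV
#'
#' @param ldscores An `ld_score_table`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_ld_scores <- function(ldscores, path) {
  utils::write.table(ldscores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
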