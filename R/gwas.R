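#' Single-variant quantitative-trait association scan
#'
#' Ordinary least squares of the phenotype on allele dosage plus covariates,
#' one variant at a time, with per-variant complete-case handling of missing
#' genotypes (no dosage imputation). Two-sided P values use the large-sample
#' normal approximation of beta/SE, which is indistinguishable from the t
#' reference at GWAS sample sizes.
#'
#' Implementation: rows missing the phenotype or any covariate are dropped
#' once; for fully observed variants the scan runs through closed-form
#' normal equations after projecting phenotype and dosages on the covariate
#' space (Frisch-Waugh), which is algebraically exact OLS; variants with
#' missing calls fall back to a per-variant QR fit on their complete cases.
#' Variants with (residual) zero dosage variance are skipped with a flag, as
#' are fits broken by collinearity.
#'
#' @param genotypes Dosage matrix (individuals x variants), NAs allowed.
#' @param phenotype Numeric vector, years (e.g. parental lifespan measured
#'   against offspring dosages, or the individual's own age).
#' @param covariates Optional numeric matrix or data.frame (e.g. PC scores,
#'   chip version indicator, sex). An intercept is always included.
#' @return An `assoc_table` data.frame: `variant`, `beta`, `se`, `z`, `p_uc`,
#'   `n`, `maf`, `missingness`, `note`. Effect estimates are on the
#'   offspring allelic-dose scale (attribute `scale = "offspring"`) until
#'   [rescale_parental()] is applied.
#' @export
assoc_quant <- function(genotypes, phenotype, covariates = NULL) {
  m <- ncol(genotypes)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- sprintf("v%05d", seq_len(m))

  X <- prepare_covariates(covariates, nrow(genotypes))
  rows <- !is.na(phenotype)
  if (!is.null(X)) rows <- rows & stats::complete.cases(X)
  y <- phenotype[rows]
  G <- if (all(rows)) genotypes else genotypes[rows, , drop = FALSE]
  Xr <- if (is.null(X)) NULL else X[rows, , drop = FALSE]
  n_all <- length(y)
  k <- if (is.null(Xr)) 0L else ncol(Xr)
  if (n_all < k + 3L) stop("too few complete rows for the model", call. = FALSE)

  miss_count <- colSums(is.na(G))
  phat <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(phat, 1 - phat)

  beta <- se <- rep(NA_real_, m)
  nn <- n_all - miss_count
  note <- rep("", m)

  qx <- NULL
  if (!is.null(Xr)) {
    qx <- qr(cbind(1, Xr))
    if (qx$rank < ncol(qx$qr)) {
      stop("covariates are collinear (rank-deficient design)", call. = FALSE)
    }
  }

  full <- which(miss_count == 0L)
  if (length(full)) {
    Gf <- if (length(full) == m) G else G[, full, drop = FALSE]
    if (is.null(qx)) {
      yc <- y - mean(y)
      syy <- sum(yc^2)
      sg <- colSums(Gf)
      sgy <- drop(crossprod(Gf, yc))
      sgg_c <- colSums(Gf * Gf) - sg^2 / n_all
      df <- n_all - 2L
    } else {
      yc <- qr.resid(qx, y)
      syy <- sum(yc^2)
      gres <- qr.resid(qx, Gf)
      sgg_c <- colSums(gres^2)
      sgy <- drop(crossprod(gres, yc))
      df <- n_all - k - 2L
    }
    ok <- sgg_c > 1e-10
    b <- ifelse(ok, sgy / sgg_c, NA_real_)
    rss <- pmax(syy - b * sgy, 0)
    s2 <- rss / df
    beta[full] <- b
    se[full] <- ifelse(ok, sqrt(s2 / sgg_c), NA_real_)
    note[full[!ok]] <- "zero_variance"
  }

  part <- which(miss_count > 0L & miss_count < n_all)
  for (j in part) {
    g <- G[, j]
    use <- !is.na(g)
    nj <- sum(use)
    pj <- k + 2L
    if (nj < pj + 1L) { note[j] <- "too_few_obs"; next }
    xm <- if (is.null(Xr)) cbind(1, g[use]) else cbind(1, Xr[use, , drop = FALSE], g[use])
    qj <- qr(xm)
    if (qj$rank < pj) { note[j] <- "collinear"; next }
    cf <- qr.coef(qj, y[use])
    res <- qr.resid(qj, y[use])
    s2 <- sum(res^2) / (nj - pj)
    xtxinv_last <- chol2inv(qr.R(qj))[pj, pj]
    beta[j] <- cf[pj]
    se[j] <- sqrt(s2 * xtxinv_last)
  }
  note[miss_count == n_all] <- "all_missing"
  note[is.na(beta) & note == ""] <- "zero_variance"

  z <- beta / se
  out <- data.frame(
    variant = ids, beta = beta, se = se, z = z,
    p_uc = 2 * stats::pnorm(-abs(z)),
    n = nn, maf = maf, missingness = miss_count / n_all,
    note = note, stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("assoc_table", "data.frame")
  attr(out, "scale") <- "offspring"
  attr(out, "trait_type") <- "quantitative"
  out
}

prepare_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  X <- as.matrix(as.data.frame(covariates))
  storage.mode(X) <- "double"
  if (nrow(X) != n) stop("covariate rows do not match genotypes", call. = FALSE)
  X
}

#' Case/control association on the tails of the age distribution
#'
#' Splits individuals into cases above the upper `case_tail` quantile of age
#' and controls at or below the median age, excluding the gap between the
#' two thresholds, then runs per-variant logistic regression of case status
#' on dosage plus covariates. This mirrors the common extreme-age
#' case/control design (e.g. a 5% tail of 86 years for men and 87 for women
#' against below-median controls of 65 and 64 years).
#'
#' @param genotypes Dosage matrix.
#' @param ages Numeric ages in years.
#' @param case_tail Upper tail fraction defining cases (default 0.05).
#' @param covariates Optional covariate matrix.
#' @return An `assoc_table` with log-odds `beta`; attribute
#'   `thresholds = c(case, control)`. Perfect-separation fits are flagged in
#'   `note`, not errors.
#' @export
assoc_case_control <- function(genotypes, ages, case_tail = 0.05,
                               covariates = NULL) {
  case_thr <- stats::quantile(ages, 1 - case_tail, na.rm = TRUE, names = FALSE)
  ctrl_thr <- stats::median(ages, na.rm = TRUE)
  status <- rep(NA_integer_, length(ages))
  status[!is.na(ages) & ages > case_thr] <- 1L
  status[!is.na(ages) & ages <= ctrl_thr] <- 0L
  use <- !is.na(status)
  if (!any(status[use] == 1L)) stop("empty case set", call. = FALSE)
  if (!any(status[use] == 0L)) stop("empty control set", call. = FALSE)

  X <- prepare_covariates(covariates, nrow(genotypes))
  if (!is.null(X)) use <- use & stats::complete.cases(X)
  yy <- status[use]
  G <- genotypes[use, , drop = FALSE]
  Xr <- if (is.null(X)) NULL else X[use, , drop = FALSE]

  m <- ncol(G)
  ids <- colnames(G)
  if (is.null(ids)) ids <- sprintf("v%05d", seq_len(m))
  beta <- se <- rep(NA_real_, m)
  nn <- integer(m)
  note <- rep("", m)
  phat <- colMeans(G, na.rm = TRUE) / 2

  for (j in seq_len(m)) {
    g <- G[, j]
    ok <- !is.na(g)
    nn[j] <- sum(ok)
    if (stats::var(g[ok]) < 1e-12) { note[j] <- "zero_variance"; next }
    xm <- if (is.null(Xr)) cbind(`(Intercept)` = 1, dosage = g[ok]) else
      cbind(`(Intercept)` = 1, Xr[ok, , drop = FALSE], dosage = g[ok])
    sep_flag <- FALSE
    fit <- withCallingHandlers(
      suppressWarnings(stats::glm.fit(xm, yy[ok], family = stats::binomial())),
      warning = function(w) sep_flag <<- TRUE
    )
    p <- ncol(xm)
    if (!fit$converged || fit$boundary) sep_flag <- TRUE
    cf <- fit$coefficients
    R <- qr.R(fit$qr)
    vc <- tryCatch(chol2inv(R), error = function(e) NULL)
    if (is.null(vc) || is.na(cf[p])) { note[j] <- "collinear"; next }
    beta[j] <- cf[p]
    se[j] <- sqrt(vc[p, p])
    if (sep_flag || abs(cf[p]) > 15) note[j] <- "separation"
  }

  z <- beta / se
  out <- data.frame(
    variant = ids, beta = beta, se = se, z = z,
    p_uc = 2 * stats::pnorm(-abs(z)),
    n = nn, maf = pmin(phat, 1 - phat),
    missingness = colMeans(is.na(G)),
    note = note, stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("assoc_table", "data.frame")
  attr(out, "scale") <- "offspring"
  attr(out, "trait_type") <- "case_control"
  attr(out, "thresholds") <- c(case = case_thr, control = ctrl_thr)
  attr(out, "n_cases") <- sum(yy == 1L)
  attr(out, "n_controls") <- sum(yy == 0L)
  out
}

#' Genomic-control correction
#'
#' The inflation factor is the ratio of the median association chi-square to
#' the median of the 1-df chi-square distribution (0.455936). Test statistics
#' are divided by `max(lambda, 1)` -- deflation is never applied -- and
#' corrected P values come from the chi-square(1) survival function.
#'
#' @param assoc An `assoc_table` with `z` (or `p_uc`) filled in.
#' @return List with `calibration` (a `gc_calibration`: `lambda`, `method`)
#'   and `assoc`, the input table with a `p_gc` column appended.
#' @export
genomic_control <- function(assoc) {
  chi2 <- assoc$z^2
  chi2 <- chi2[is.finite(chi2)]
  if (!length(chi2)) stop("no usable test statistics", call. = FALSE)
  lambda <- stats::median(chi2) / CHISQ1_MEDIAN
  corr <- assoc$z^2 / max(lambda, 1)
  assoc$p_gc <- stats::pchisq(corr, df = 1, lower.tail = FALSE)
  calib <- list(lambda = lambda,
                method = "median(chi2) / 0.455936; correction floored at 1")
  class(calib) <- "gc_calibration"
  list(calibration = calib, assoc = assoc)
}

CHISQ1_MEDIAN <- 0.455936

#' @export
print.gc_calibration <- function(x, ...) {
  cat(sprintf("Genomic control: lambda = %.4f (%s)\n", x$lambda, x$method))
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests.
#' @return `alpha / m`. With the 540,852 variants of a filtered array panel
#'   and alpha = 0.05 this is 9.24e-8.
#' @export
significance_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' Rescale offspring-dose estimates to the parental allelic dose
#'
#' The genotyped offspring carries half the expected allelic dose of the
#' phenotyped parent, so effect and SE are doubled (z and P are unchanged)
#' and any per-SNP variance-explained or heritability column is multiplied
#' by four. The rescaling is applied exactly once: the table carries a scale
#' attribute and a second call is an error.
#'
#' @param assoc An `assoc_table` on the offspring scale.
#' @return The table on the parental scale (`scale = "parental"`).
#' @export
rescale_parental <- function(assoc) {
  if (identical(attr(assoc, "scale"), "parental")) {
    stop("assoc table is already on the parental scale", call. = FALSE)
  }
  assoc$beta <- assoc$beta * 2
  assoc$se <- assoc$se * 2
  for (col in intersect(c("h2_snp", "var_explained"), names(assoc))) {
    assoc[[col]] <- assoc[[col]] * 4
  }
  attr(assoc, "scale") <- "parental"
  assoc
}

#' Per-SNP variance explained
#'
#' Adds a `var_explained` column, beta^2 * 2 p (1-p) divided by the
#' phenotypic variance, on whichever scale the table currently carries.
#'
#' @param assoc An `assoc_table`.
#' @param phenotypic_variance Total phenotypic variance (yr^2).
#' @return The table with `var_explained` appended (as a fraction).
#' @export
add_variance_explained <- function(assoc, phenotypic_variance) {
  assoc$var_explained <- assoc$beta^2 * 2 * assoc$maf * (1 - assoc$maf) /
    phenotypic_variance
  assoc
}

#' Default birth-cohort slices
#'
#' The eleven 4--8 year windows spanning the 1886--1940 cohorts:
#' 1886-1894, 1894-1902, 1902-1908, 1908-1912, 1912-1916, 1916-1920,
#' 1920-1924, 1924-1928, 1928-1932, 1932-1936, 1935-1940.
#'
#' @return A list of `c(start, end)` integer pairs.
#' @export
default_birth_cohort_slices <- function() {
  list(c(1886L, 1894L), c(1894L, 1902L), c(1902L, 1908L), c(1908L, 1912L),
       c(1912L, 1916L), c(1916L, 1920L), c(1920L, 1924L), c(1924L, 1928L),
       c(1928L, 1932L), c(1932L, 1936L), c(1935L, 1940L))
}

#' Birth-cohort-sliced effect estimates for one variant
#'
#' Reruns the quantitative association for a single variant within each
#' birth-year slice (inclusive bounds; consecutive default slices share
#' their boundary year, as the slice list is defined). Slices with fewer
#' than two informative individuals are flagged empty.
#'
#' @param genotypes Dosage matrix.
#' @param cohort `cohort_table` aligned with `genotypes` rows; `birth_year`
#'   and `lifespan` are used.
#' @param variant Variant id (column name) to follow across cohorts.
#' @param slices List of `c(start, end)` birth-year pairs; defaults to
#'   [default_birth_cohort_slices()].
#' @param covariates Optional covariates.
#' @return data.frame with one row per slice: `start`, `end`, `beta`, `se`,
#'   `n`, `note`.
#' @export
cohort_slice_effects <- function(genotypes, cohort, variant,
                                 slices = default_birth_cohort_slices(),
                                 covariates = NULL) {
  j <- match(variant, colnames(genotypes))
  if (is.na(j)) stop("variant not found: ", variant, call. = FALSE)
  X <- prepare_covariates(covariates, nrow(genotypes))
  out <- data.frame(start = vapply(slices, `[`, integer(1), 1L),
                    end = vapply(slices, `[`, integer(1), 2L),
                    beta = NA_real_, se = NA_real_, n = 0L, note = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    rows <- which(cohort$birth_year >= s[1] & cohort$birth_year <= s[2] &
                    !is.na(cohort$lifespan))
    g <- genotypes[rows, j]
    inf <- sum(!is.na(g))
    out$n[i] <- inf
    if (inf < 2L) { out$note[i] <- "empty"; next }
    tab <- assoc_quant(genotypes[rows, j, drop = FALSE],
                       cohort$lifespan[rows],
                       if (is.null(X)) NULL else X[rows, , drop = FALSE])
    out$beta[i] <- tab$beta[1]
    out$se[i] <- tab$se[1]
    out$n[i] <- tab$n[1]
    out$note[i] <- tab$note[1]
  }
  out
}

#' Allele frequency by lifespan class and birth cohort
#'
#' Bins parents into (birth-cohort slice) x (lifespan class) cells and
#' reports the minor-allele frequency of the linked offspring genotypes in
#' each cell; the minor allele is fixed globally from the full sample so the
#' grid is comparable across cells. Cells with fewer than `min_n`
#' individuals are masked to NA (default 500).
#'
#' @param genotypes Dosage matrix.
#' @param cohort Aligned `cohort_table`.
#' @param variant Variant id.
#' @param lifespan_bins Numeric break points for lifespan classes (passed to
#'   `cut`, right-closed).
#' @param cohort_slices List of `c(start, end)` birth-year pairs.
#' @param min_n Minimum cell occupancy below which the cell is masked.
#' @return List with matrices `freq` (slices x bins, masked) and `n`.
#' @export
af_by_lifespan_grid <- function(genotypes, cohort, variant,
                                lifespan_bins,
                                cohort_slices = default_birth_cohort_slices(),
                                min_n = 500L) {
  j <- match(variant, colnames(genotypes))
  if (is.na(j)) stop("variant not found: ", variant, call. = FALSE)
  g <- genotypes[, j]
  minor_is_alt <- mean(g, na.rm = TRUE) / 2 <= 0.5
  mg <- if (minor_is_alt) g else 2L - g

  bin <- cut(cohort$lifespan, breaks = lifespan_bins, include.lowest = TRUE)
  ns <- length(cohort_slices)
  nb <- nlevels(bin)
  freq <- nmat <- matrix(NA_real_, ns, nb,
                         dimnames = list(
                           vapply(cohort_slices,
                                  function(s) paste(s, collapse = "-"),
                                  character(1)),
                           levels(bin)))
  for (i in seq_len(ns)) {
    s <- cohort_slices[[i]]
    in_slice <- cohort$birth_year >= s[1] & cohort$birth_year <= s[2]
    for (b in seq_len(nb)) {
      rows <- which(in_slice & !is.na(bin) & as.integer(bin) == b & !is.na(mg))
      nmat[i, b] <- length(rows)
      if (length(rows) >= min_n) freq[i, b] <- mean(mg[rows]) / 2
    }
  }
  list(freq = freq, n = nmat)
}

#' @export
print.assoc_table <- function(x, ..., top = 6L) {
  cat(sprintf("Association scan: %d variants (%s trait, %s scale)\n",
              nrow(x), attr(x, "trait_type") %||% "quantitative",
              attr(x, "scale") %||% "offspring"))
  ord <- order(x$p_uc)
  print.data.frame(utils::head(x[ord, setdiff(names(x), "note")], top),
                   digits = 4, row.names = FALSE)
  invisible(x)
}
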