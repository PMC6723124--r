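#' One replicate of the transmission power simulation
#'
#' Simulates a single additive locus segregating at Hardy-Weinberg
#' equilibrium in a large random-mating population: parental genotypes are
#' drawn at frequency `p`, the parental trait is `beta_parental * dosage`
#' plus normal environmental noise topping the variance up to
#' `total_variance`, each offspring receives one Mendelian allele from the
#' phenotyped parent and one from a random mate, and the parental phenotype
#' is regressed on the offspring dosage. The expected offspring-scale slope
#' is `beta_parental / 2`.
#'
#' @param p Effect-allele frequency, 0 < p < 1.
#' @param beta_parental Additive effect in years per allele, parental scale.
#' @param n Number of parent-offspring pairs.
#' @param total_variance Total phenotypic variance (yr^2), default 166.2.
#' @param alpha Two-sided significance threshold, default 5.0e-8.
#' @param seed Optional seed for this replicate.
#' @return List: `beta_offspring`, `beta_parental_hat` (slope on the
#'   parent's own dosage), `p_value` (offspring regression), `significant`.
#' @export
power_replicate <- function(p, beta_parental, n, total_variance = 166.2,
                            alpha = 5e-8, seed = NULL) {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  var_g <- beta_parental^2 * 2 * p * (1 - p)
  if (total_variance <= var_g) {
    stop("total_variance must exceed the genetic variance", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  gp <- stats::rbinom(n, 2L, p)
  pheno <- beta_parental * gp + stats::rnorm(n, 0, sqrt(total_variance - var_g))
  mate <- stats::rbinom(n, 2L, p)
  go <- mendelian_gamete(gp) + mendelian_gamete(mate)

  fo <- simple_ols(go, pheno)
  fp <- simple_ols(gp, pheno)
  list(beta_offspring = fo$beta,
       beta_parental_hat = fp$beta,
       p_value = fo$p,
       significant = is.finite(fo$p) && fo$p < alpha)
}

# closed-form simple linear regression with normal-approximation P
simple_ols <- function(x, y) {
  n <- length(y)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx < 1e-12) return(list(beta = NA_real_, se = NA_real_, p = NA_real_))
  b <- sum(xc * y) / sxx
  rss <- sum((y - mean(y) - b * xc)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  z <- b / se
  list(beta = b, se = se, p = 2 * stats::pnorm(-abs(z)))
}

#' Power grid over allele frequency, effect size and cohort size
#'
#' Runs `reps` independent transmission replicates per (p, beta, N) cell and
#' reports power as the fraction of replicates whose offspring-dosage
#' regression reaches `alpha`, alongside the mean offspring- and
#' parental-scale effect estimates. Fresh parents and mates are drawn each
#' replicate. Fifty replicates per cell is the conventional grid density;
#' the frequency range 0.001--0.5, effects 0.06--3.8 years and cohorts of
#' 80,000--480,000 span the design space of a consumer-genomics lifespan
#' study.
#'
#' @param ps,betas,ns Numeric vectors of allele frequencies, parental-scale
#'   effects (years/allele) and cohort sizes; the grid is their cross
#'   product.
#' @param reps Replicates per cell (>= 1).
#' @param alpha Significance threshold (default 5.0e-8).
#' @param total_variance Total phenotypic variance (yr^2).
#' @param seed Integer seed for the whole grid.
#' @return A `power_grid` data.frame: `p`, `beta`, `n`, `reps`, `alpha`,
#'   `power`, `mean_beta_offspring`, `mean_beta_parental`.
#' @export
power_grid <- function(ps, betas, ns, reps = 50L, alpha = 5e-8,
                       total_variance = 166.2, seed = 1L) {
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  set.seed(seed)
  cells <- expand.grid(p = ps, beta = betas, n = ns,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    hits <- 0L
    bo <- bp <- numeric(reps)
    for (r in seq_len(reps)) {
      rep <- power_replicate(cells$p[i], cells$beta[i], cells$n[i],
                             total_variance, alpha)
      hits <- hits + as.integer(rep$significant)
      bo[r] <- rep$beta_offspring
      bp[r] <- rep$beta_parental_hat
    }
    c(power = hits / reps, mean_beta_offspring = mean(bo),
      mean_beta_parental = mean(bp))
  })
  res <- do.call(rbind, res)
  out <- cbind(cells, reps = reps, alpha = alpha, as.data.frame(res))
  class(out) <- c("power_grid", "data.frame")
  attr(out, "total_variance") <- total_variance
  out
}

#' Analytic power approximation for the offspring-dosage regression
#'
#' Non-centrality `NCP = N (beta/2)^2 2p(1-p) / sigma^2` against the
#' chi-square(1) threshold at `alpha`; used as the closed-form check on the
#' Monte-Carlo grid.
#'
#' @inheritParams power_replicate
#' @return Power in \[0, 1\].
#' @export
analytic_power <- function(p, beta_parental, n, total_variance = 166.2,
                           alpha = 5e-8) {
  ncp <- n * (beta_parental / 2)^2 * 2 * p * (1 - p) / total_variance
  crit <- stats::qchisq(alpha, df = 1, lower.tail = FALSE)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Observed effect dilution across a power grid
#'
#' Mean over grid cells of (mean offspring-scale estimate) / (generating
#' parental effect). Under Mendelian transmission with one phenotyped parent
#' this ratio is 1/2 independent of allele frequency. Cells with a zero
#' generating effect are excluded with a warning.
#'
#' @param grid A `power_grid`.
#' @return Single numeric dilution ratio.
#' @export
dilution_ratio <- function(grid) {
  zero <- grid$beta == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with beta = 0 excluded from dilution ratio")
    grid <- grid[!zero, , drop = FALSE]
  }
  if (!nrow(grid)) stop("no cells with nonzero effect", call. = FALSE)
  mean(grid$mean_beta_offspring / grid$beta)
}

#' Estimate assumed right-censorship from a baseline birth cohort
#'
#' In a snapshot taken at `snapshot_year`, an individual born in year `y`
#' can only have a complete (observed) lifespan up to `c_y = snapshot_year -
#' y`. Using the pooled lifespan distribution `F` of a baseline cohort old
#' enough to be fully observed, the number of still-alive (assumed
#' right-censored) individuals in year `y` is estimated by inflating the
#' observed complete count by the odds of the baseline mass at or beyond the
#' observable maximum: `alive = n_complete(y) * (1 - F(c_y)) / F(c_y)` with
#' `F(c) = P(lifespan < c)`. The annual assumed-censored fraction is
#' `alive / (alive + n_complete)`, and the cumulative fraction aggregates
#' counts from the first target year. Years whose observable maximum reaches
#' the top of the lifespan window contribute zero; years where the baseline
#' has no mass below `c_y` are flagged undefined.
#'
#' This odds-style inflation is one reconstruction of the baseline
#' principle; it is exposed behind this named interface so alternative
#' estimators can be slotted in.
#'
#' @param cohort A `cohort_table` as observed (missing `lifespan` = no death
#'   record).
#' @param baseline_years `c(first, last)` birth years of the fully observed
#'   baseline (default 1886--1910).
#' @param target_years `c(first, last)` birth years to estimate (default
#'   1911--1940).
#' @param snapshot_year Snapshot year (default 2016).
#' @param lifespan_window Admissible lifespan range (default `c(40, 120)`).
#' @return A `censorship_estimate` data.frame: `birth_year`, `n_complete`,
#'   `est_alive`, `annual_fraction`, `cumulative_fraction`, `note`.
#' @export
estimate_censorship <- function(cohort,
                                baseline_years = c(1886L, 1910L),
                                target_years = c(1911L, 1940L),
                                snapshot_year = 2016L,
                                lifespan_window = c(40, 120)) {
  ls_ok <- !is.na(cohort$lifespan) &
    cohort$lifespan >= lifespan_window[1] & cohort$lifespan <= lifespan_window[2]
  base <- cohort$lifespan[ls_ok &
                            cohort$birth_year >= baseline_years[1] &
                            cohort$birth_year <= baseline_years[2]]
  if (!length(base)) stop("baseline cohort contains no complete lifespans",
                          call. = FALSE)

  years <- seq(target_years[1], target_years[2])
  n_complete <- est_alive <- annual <- numeric(length(years))
  note <- character(length(years))
  for (i in seq_along(years)) {
    y <- years[i]
    cy <- snapshot_year - y
    n_complete[i] <- sum(ls_ok & cohort$birth_year == y)
    if (cy >= lifespan_window[2]) {
      est_alive[i] <- 0; annual[i] <- 0; next
    }
    Fc <- mean(base < cy)
    if (Fc == 0) {
      est_alive[i] <- NA_real_; annual[i] <- NA_real_
      note[i] <- "baseline_mass_zero"
      next
    }
    est_alive[i] <- n_complete[i] * (1 - Fc) / Fc
    annual[i] <- if (est_alive[i] + n_complete[i] > 0) {
      est_alive[i] / (est_alive[i] + n_complete[i])
    } else 1 - Fc
  }
  cum_alive <- cumsum(ifelse(is.na(est_alive), 0, est_alive))
  cum_n <- cumsum(n_complete)
  cumulative <- ifelse(cum_alive + cum_n > 0, cum_alive / (cum_alive + cum_n),
                       0)
  out <- data.frame(birth_year = years, n_complete = n_complete,
                    est_alive = est_alive, annual_fraction = annual,
                    cumulative_fraction = cumulative, note = note,
                    stringsAsFactors = FALSE)
  class(out) <- c("censorship_estimate", "data.frame")
  attr(out, "baseline_years") <- baseline_years
  attr(out, "snapshot_year") <- snapshot_year
  out
}

#' Summary-statistic identifiability ratio
#'
#' The re-identification power of GWAS summary statistics grows with the
#' ratio of reported SNPs `m` to cohort size `n`, proportionally to
#' `sqrt(m/n)`.
#'
#' @param m Number of reported SNP statistics.
#' @param n Cohort size (>= 1).
#' @return List with `ratio = m/n` and `sqrt_ratio = sqrt(m/n)`.
#' @export
privacy_ratio <- function(m, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (m < 0) stop("m must be >= 0", call. = FALSE)
  list(ratio = m / n, sqrt_ratio = sqrt(m / n))
}

#' @export
print.power_grid <- function(x, ...) {
  cat(sprintf("Power grid: %d cells, %d replicates each, alpha = %g, total variance %.1f yr^2\n",
              nrow(x), x$reps[1], x$alpha[1], attr(x, "total_variance")))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
print.censorship_estimate <- function(x, ...) {
  cat(sprintf("Assumed-censorship estimate (baseline %d-%d, snapshot %d)\n",
              attr(x, "baseline_years")[1], attr(x, "baseline_years")[2],
              attr(x, "snapshot_year")))
  cat(sprintf("  cumulative assumed-censored fraction: %.3f\n",
              x$cumulative_fraction[nrow(x)]))
  invisible(x)
}
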