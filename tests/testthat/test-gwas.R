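test_that("constructed exact fit recovers a unit slope", {
  g <- matrix(c(0, 1, 2, 1, 0), ncol = 1, dimnames = list(NULL, "v1"))
  tab <- assoc_quant(g, c(1, 2, 3, 2, 1))
  expect_equal(tab$beta, 1.0)
  expect_equal(tab$n, 5L)
})

test_that("association estimates match the per-variant least-squares oracle", {
  set.seed(101)
  n <- 1000L
  m <- 50L
  g <- hwe_genotypes(n, runif(m, 0.05, 0.5))
  colnames(g) <- sprintf("v%02d", seq_len(m))
  g[sample(length(g), 1500)] <- NA       # per-variant complete-case path
  covs <- cbind(pc1 = rnorm(n), chip = rbinom(n, 1, 0.5))
  y <- rnorm(n, 80, 12) + 0.4 * covs[, 1]

  tab <- assoc_quant(g, y, covariates = covs)
  for (j in seq_len(m)) {
    fit <- lm(y ~ covs + g[, j])
    cf <- summary(fit)$coefficients
    expect_equal(tab$beta[j], unname(cf[4, 1]), tolerance = 1e-8)
    expect_equal(tab$se[j], unname(cf[4, 2]), tolerance = 1e-8)
    expect_equal(tab$n[j], sum(!is.na(g[, j])))
  }
  expect_equal(tab$z, tab$beta / tab$se)
  expect_true(all(tab$p_uc > 0 & tab$p_uc <= 1))
})

test_that("null P values are uniform and zero-variance variants are skipped", {
  set.seed(37)
  n <- 500L
  m <- 5000L
  g <- hwe_genotypes(n, runif(m, 0.1, 0.5))
  colnames(g) <- sprintf("v%04d", seq_len(m))
  y <- sample(rnorm(n, 76, 13))  # permuted phenotype, independent of g
  tab <- assoc_quant(g, y)
  frac <- mean(tab$p_uc < 0.05, na.rm = TRUE)
  se <- sqrt(0.05 * 0.95 / m)
  expect_lt(abs(frac - 0.05), 3 * se)

  gz <- cbind(g[, 1:3], zero = 0L)
  tabz <- assoc_quant(gz, y)
  expect_true(is.na(tabz$beta[4]))
  expect_equal(tabz$note[4], "zero_variance")
})

test_that("offspring-scale estimate is half the parental effect through the scan", {
  reps <- 25
  est <- vapply(seq_len(reps), function(r) {
    cfg <- one_locus_config(n = 20000L, beta = 0.75, freq = 0.2,
                            seed = 500 + r)
    panel <- simulate_variant_panel(cfg)
    par <- simulate_parent_cohort(panel, cfg, "paternal_lifespan")
    off <- transmit_offspring(par$genotypes, panel, cfg)
    assoc_quant(off[, 1, drop = FALSE], par$cohort$lifespan)$beta
  }, numeric(1))
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 0.375), 3 * se)
})

test_that("age-tail case/control split follows the stated quantile rule", {
  ages <- 1:100
  g <- matrix(rbinom(100 * 3, 2, 0.3), 100, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  tab <- assoc_case_control(g, ages, case_tail = 0.05)
  expect_equal(attr(tab, "n_cases"), 5L)       # ages 96-100
  expect_equal(attr(tab, "n_controls"), 50L)   # ages 1-50 (<= median)
  thr <- attr(tab, "thresholds")
  expect_equal(unname(thr["control"]), 50.5)
  expect_error(assoc_case_control(g, rep(50, 100)), "empty case")
})

test_that("case/control scan is calibrated under the null", {
  set.seed(71)
  n <- 2000L
  m <- 5000L
  g <- hwe_genotypes(n, runif(m, 0.1, 0.5))
  colnames(g) <- sprintf("v%04d", seq_len(m))
  ages <- rnorm(n, 60, 15)
  tab <- assoc_case_control(g, ages, case_tail = 0.05)
  lam <- genomic_control(tab)$calibration$lambda
  expect_lt(abs(lam - 1), 0.05)
})

test_that("genomic control uses the chi-square(1) median and floors at 1", {
  mk <- function(chi2) {
    structure(data.frame(variant = sprintf("v%03d", seq_along(chi2)),
                         beta = sqrt(chi2), se = 1, z = sqrt(chi2),
                         p_uc = 2 * pnorm(-sqrt(chi2)), n = 100L,
                         maf = 0.2, missingness = 0, note = ""),
              class = c("assoc_table", "data.frame"), scale = "offspring")
  }
  # median exactly at the null median: lambda = 1
  v <- c(seq(0.1, 0.45, length.out = 10), 0.455936,
         seq(0.5, 3, length.out = 10))
  expect_equal(genomic_control(mk(v))$calibration$lambda, 1.0)

  # inflated statistics reproduce the anchor lambda
  expect_equal(genomic_control(mk(v * 1.084))$calibration$lambda, 1.084,
               tolerance = 1e-10)

  # correction divides by lambda: chi2 30 at lambda 1.2 -> 25
  v2 <- c(seq(0.1, 0.5, length.out = 10), 1.2 * 0.455936,
          seq(0.7, 3, length.out = 9), 30)
  res <- genomic_control(mk(v2))
  expect_equal(res$calibration$lambda, 1.2, tolerance = 1e-10)
  expect_equal(res$assoc$p_gc[nrow(res$assoc)],
               pchisq(25, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(res$assoc$p_gc[nrow(res$assoc)], 5.73e-7, tolerance = 1e-3)

  # deflation is never applied
  low <- mk(v * 0.5)
  expect_equal(genomic_control(low)$assoc$p_gc, low$p_uc, tolerance = 1e-12)
})

test_that("Bonferroni threshold reproduces the genome-wide cutoff", {
  expect_equal(significance_threshold(0.05, 540852), 9.24e-8,
               tolerance = 5e-3)
  expect_equal(significance_threshold(0.05, 1), 0.05)
  expect_error(significance_threshold(0.05, 0), ">= 1")
})

test_that("parental rescaling doubles effects once and only once", {
  tab <- structure(
    data.frame(variant = "rs1", beta = 0.325, se = 0.045,
               z = 0.325 / 0.045, p_uc = 2 * pnorm(-0.325 / 0.045),
               n = 100000L, maf = 0.49, missingness = 0, note = "",
               stringsAsFactors = FALSE),
    class = c("assoc_table", "data.frame"), scale = "offspring")
  tab <- add_variance_explained(tab, phenotypic_variance = 166.2)
  ve_off <- tab$var_explained
  out <- rescale_parental(tab)
  expect_equal(out$beta, 0.65)
  expect_equal(out$se, 0.09)
  expect_equal(out$z, tab$z)          # z and P untouched
  expect_equal(out$p_uc, tab$p_uc)
  expect_equal(out$var_explained, 4 * ve_off)
  expect_error(rescale_parental(out), "already")

  zero <- tab; zero$beta <- 0
  expect_equal(rescale_parental(zero)$beta, 0)
})

test_that("cohort slices follow the canonical windows and recover local effects", {
  slices <- default_birth_cohort_slices()
  expect_length(slices, 11L)
  expect_equal(slices[[1]], c(1886L, 1894L))
  expect_equal(slices[[11]], c(1935L, 1940L))

  set.seed(83)
  n <- 9000L
  birth <- sample(1886:1940, n, replace = TRUE)
  g <- matrix(rbinom(n, 2, 0.3), ncol = 1, dimnames = list(NULL, "v1"))
  y <- ifelse(birth < 1920, 2 * g[, 1], 0) + rnorm(n, 70, 5)
  cohort <- data.frame(iid = as.character(seq_len(n)), birth_year = birth,
                       lifespan = y, stringsAsFactors = FALSE)
  eff <- cohort_slice_effects(g, cohort, "v1")
  pre <- eff$end <= 1916   # slices fully inside the effect era
  post <- eff$start >= 1920
  expect_true(all(abs(eff$beta[pre] - 2) <= 2 * eff$se[pre]))
  expect_true(all(abs(eff$beta[post]) <= 2 * eff$se[post]))

  # a single slice equals the plain scan on the filtered cohort
  one <- cohort_slice_effects(g, cohort, "v1", slices = list(c(1900L, 1910L)))
  rows <- birth >= 1900 & birth <= 1910
  ref <- assoc_quant(g[rows, , drop = FALSE], y[rows])
  expect_equal(one$beta, ref$beta)
  expect_equal(one$se, ref$se)

  empty <- cohort_slice_effects(g, cohort, "v1",
                                slices = list(c(1800L, 1801L)))
  expect_equal(empty$note, "empty")
})

test_that("allele-frequency grid masks sparse cells and sees enrichment", {
  set.seed(91)
  n <- 12000L
  birth <- sample(1886:1940, n, replace = TRUE)
  life <- runif(n, 40, 100)
  g <- rbinom(n, 2, 0.25)
  # enrich the minor allele among long-lived parents born 1886-1894
  hot <- birth <= 1894 & life > 80
  g[hot] <- rbinom(sum(hot), 2, 0.45)
  gm <- matrix(g, ncol = 1, dimnames = list(NULL, "v1"))
  cohort <- data.frame(iid = as.character(seq_len(n)), birth_year = birth,
                       lifespan = life, stringsAsFactors = FALSE)

  grid <- af_by_lifespan_grid(gm, cohort, "v1",
                              lifespan_bins = c(40, 60, 80, 100),
                              min_n = 30L)
  hot_cell <- grid$freq["1886-1894", "(80,100]"]
  cold_cell <- grid$freq["1920-1924", "(80,100]"]
  n_hot <- grid$n["1886-1894", "(80,100]"]
  se <- sqrt(0.45 * 0.55 / (2 * n_hot))
  expect_lt(abs(hot_cell - 0.45), 3 * se)
  expect_lt(cold_cell, 0.35)

  # min_n masks any cell below the occupancy floor, 499 < 500 included
  grid500 <- af_by_lifespan_grid(gm, cohort, "v1",
                                 lifespan_bins = c(40, 60, 80, 100),
                                 min_n = 500L)
  under <- grid500$n < 500
  expect_true(all(is.na(grid500$freq[under])))
  expect_true(all(!is.na(grid500$freq[!under])))

  # flat variant: grid flat within binomial noise
  set.seed(92)
  gflat <- matrix(rbinom(n, 2, 0.3), ncol = 1, dimnames = list(NULL, "v1"))
  gridf <- af_by_lifespan_grid(gflat, cohort, "v1",
                               lifespan_bins = c(40, 70, 100), min_n = 100L)
  ok <- !is.na(gridf$freq)
  zsc <- (gridf$freq[ok] - 0.3) / sqrt(0.3 * 0.7 / (2 * gridf$n[ok]))
  expect_lt(max(abs(zsc)), 4)
})
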