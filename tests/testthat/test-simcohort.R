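test_that("variant panel carries configured effects and is reproducible", {
  cfg <- one_locus_config(beta = 0.75, freq = 0.2, seed = 11)
  panel <- simulate_variant_panel(cfg)
  expect_equal(panel$beta_paternal_lifespan[1], 0.75)
  expect_equal(panel$freq[1], 0.2)
  expect_true(all(panel$freq >= 0.001 & panel$freq <= 0.5))
  # positions strictly increasing within chromosome
  for (cc in unique(panel$chrom)) {
    expect_true(all(diff(panel$pos[panel$chrom == cc]) > 0))
  }
  expect_identical(panel, simulate_variant_panel(cfg))
  cfg2 <- one_locus_config(beta = 0.75, freq = 0.2, seed = 12)
  expect_false(identical(simulate_variant_panel(cfg2), panel))
})

test_that("maf spectrum draws match the configured uniform distribution", {
  cfg <- sim_config(10L, 10000L,
                    maf_spectrum = list(dist = "uniform", min = 0.01, max = 0.5),
                    seed = 3)
  panel <- simulate_variant_panel(cfg)
  ks <- suppressWarnings(ks.test(panel$freq, "punif", 0.01, 0.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(10, 5, missing_death_base_rate = 1.2),
               "probabilities")
  expect_error(sim_config(10, 5, total_phenotypic_variance = -1), "variance")
  expect_error(sim_config(10, 5, lifespan_window = c(120, 40)), "ordered")
  expect_error(sim_config(10, 5, causal_effects = data.frame(
    variant = 9L, trait = "age", beta = 1)), "out of range")
})

test_that("parental genotypes fit Hardy-Weinberg proportions", {
  cfg <- one_locus_config(n = 50000L, beta = 0, freq = 0.5, seed = 21)
  panel <- simulate_variant_panel(cfg)
  par <- simulate_parent_cohort(panel, cfg, "paternal_lifespan")
  g <- par$genotypes[, 1]
  obs <- tabulate(g + 1L, 3L)
  exp_p <- c(0.25, 0.5, 0.25) * length(g)
  chi2 <- sum((obs - exp_p)^2 / exp_p)
  expect_gt(pchisq(chi2, df = 2, lower.tail = FALSE), 0.01)
})

test_that("null-model lifespan variance and window match the configuration", {
  cfg <- sim_config(20000L, 5L, seed = 22)
  panel <- simulate_variant_panel(cfg)
  par <- simulate_parent_cohort(panel, cfg, "paternal_lifespan")
  ls <- par$cohort$lifespan
  expect_true(all(ls >= 40 & ls <= 120))
  expect_lt(abs(var(ls) - 166.2) / 166.2, 0.05)
  expect_lt(abs(median(ls) - 76), 0.5)
  # lifespan identity against death year
  expect_equal(par$cohort$death_year - par$cohort$birth_year, ls)
  mat <- simulate_parent_cohort(panel, cfg, "maternal_lifespan")
  expect_lt(abs(median(mat$cohort$lifespan) - 82), 0.5)
})

test_that("genetic variance exceeding the phenotypic total is rejected", {
  cfg <- one_locus_config(n = 50L, beta = 50, freq = 0.5, seed = 1)
  panel <- simulate_variant_panel(cfg)
  expect_error(simulate_parent_cohort(panel, cfg, "paternal_lifespan"),
               "exceeds total")
})

test_that("Mendelian gametes obey forced and fair-coin rules", {
  expect_identical(mendelian_gamete(rep(0L, 100)), rep(0L, 100))
  expect_identical(mendelian_gamete(rep(2L, 100)), rep(1L, 100))
  set.seed(5)
  tr <- mendelian_gamete(rep(1L, 200000))
  se <- sqrt(0.25 / 200000)
  expect_lt(abs(mean(tr) - 0.5), 4 * se)
})

test_that("parent-offspring dosage correlation is one half", {
  cfg <- one_locus_config(n = 100000L, beta = 0, freq = 0.3, seed = 31)
  panel <- simulate_variant_panel(cfg)
  par <- simulate_parent_cohort(panel, cfg, "paternal_lifespan")
  off <- transmit_offspring(par$genotypes, panel, cfg)
  expect_lt(abs(cor(par$genotypes[, 1], off[, 1]) - 0.5), 0.01)
})

test_that("offspring regression slope is diluted to half the parental effect", {
  # Monte Carlo across the module path vs the closed form cov/var = beta/2
  reps <- 20
  slopes <- vapply(seq_len(reps), function(r) {
    cfg <- one_locus_config(n = 20000L, beta = 2, freq = 0.3, seed = 100 + r)
    panel <- simulate_variant_panel(cfg)
    par <- simulate_parent_cohort(panel, cfg, "paternal_lifespan")
    off <- transmit_offspring(par$genotypes, panel, cfg)
    coef(lm(par$cohort$lifespan ~ off[, 1]))[2]
  }, numeric(1))
  se <- sd(slopes) / sqrt(reps)
  expect_lt(abs(mean(slopes) - 1), 3 * se)
})

test_that("observation model censors, loses records and preserves lifespans", {
  # all true deaths precede the snapshot; record loss is the only source of NA
  cfg <- sim_config(30000L, 2L, birth_year_range = c(1886L, 1890L),
                    missing_death_base_rate = 1 / 3, seed = 41)
  panel <- simulate_variant_panel(cfg)
  par <- simulate_parent_cohort(panel, cfg, "paternal_lifespan")
  expect_true(all(par$cohort$death_year <= 2016))
  obs <- apply_observation_model(par$cohort, cfg)
  frac <- mean(is.na(obs$death_year))
  se <- sqrt((1 / 3) * (2 / 3) / nrow(obs))
  expect_lt(abs(frac - 1 / 3), 3 * se)
  # conservation: retained lifespans unchanged
  kept <- !is.na(obs$lifespan)
  expect_identical(obs$lifespan[kept], par$cohort$lifespan[kept])
  expect_true(all(obs$chip %in% c("v1", "v2")))

  # forced censorship of post-snapshot deaths; no loss when the rate is zero
  cfg0 <- sim_config(500L, 2L, birth_year_range = c(1938L, 1940L),
                     missing_death_base_rate = 0, seed = 42)
  par0 <- simulate_parent_cohort(simulate_variant_panel(cfg0), cfg0,
                                 "paternal_lifespan")
  obs0 <- apply_observation_model(par0$cohort, cfg0)
  post <- par0$cohort$death_year > 2016
  expect_true(all(is.na(obs0$death_year[post])))
  expect_true(all(!is.na(obs0$death_year[!post])))
})

test_that("identical configurations give identical pipelines", {
  run <- function() {
    cfg <- one_locus_config(n = 300L, beta = 1, freq = 0.25, seed = 77,
                            genotype_missing_rate = 0.05)
    panel <- simulate_variant_panel(cfg)
    par <- simulate_parent_cohort(panel, cfg, "paternal_lifespan")
    off <- transmit_offspring(par$genotypes, panel, cfg)
    apply_observation_model(par$cohort, cfg, off)
  }
  expect_identical(run(), run())
})

test_that("age cohort ages are consistent with birth years", {
  cfg <- sim_config(2000L, 5L, seed = 51)
  panel <- simulate_variant_panel(cfg)
  ind <- simulate_parent_cohort(panel, cfg, "age")
  co <- ind$cohort
  expect_true(all(co$age_at_snapshot == 2016 - co$birth_year))
  expect_true(all(co$age_at_snapshot >= 2016 - 1940 &
                    co$age_at_snapshot <= 2016 - 1886))
  expect_true(all(is.na(co$death_year)))
})

test_that("population structure differentiates subpopulation frequencies", {
  cfg <- sim_config(2000L, 50L, n_subpops = 2L, fst = 0.1, seed = 61)
  panel <- simulate_variant_panel(cfg)
  sf <- attr(panel, "subpop_freq")
  expect_equal(dim(sf), c(50L, 2L))
  par <- simulate_parent_cohort(panel, cfg, "paternal_lifespan")
  expect_setequal(unique(par$cohort$subpop), c(1L, 2L))
  # empirical per-subpop frequencies track the Balding-Nichols draws
  g1 <- colMeans(par$genotypes[par$cohort$subpop == 1L, ]) / 2
  g2 <- colMeans(par$genotypes[par$cohort$subpop == 2L, ]) / 2
  expect_gt(cor(g1 - g2, sf[, 1] - sf[, 2]), 0.9)
})

test_that("simulated relatedness plants close pairs on a low background", {
  ids <- sprintf("i%03d", 1:40)
  rel <- simulate_relatedness(ids, n_related_pairs = 3L, seed = 9)
  expect_equal(nrow(rel), choose(40, 2))
  expect_equal(sum(rel$cm > 300), 3L)
  expect_true(all(rel$cm[rel$cm > 300] == 1772))
})
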