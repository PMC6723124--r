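#' Simulation configuration for synthetic parent-offspring cohorts
#'
#' Bundles every parameter of the synthetic study: the variant panel, the
#' additive genetic architecture, the phenotype model, the birth-cohort and
#' snapshot structure, and the observation model (record loss, genotype
#' missingness, chip versions).
#'
#' The defaults encode the study conditions the rest of the package assumes:
#' total phenotypic variance of lifespan 166.2 yr\eqn{^2}, birth cohorts
#' 1886--1940 observed at a 2016 snapshot, lifespan restricted to 40--120
#' years, sex-specific median lifespans of 76 (paternal) and 82 (maternal)
#' years, and a baseline probability of 1/3 that a pre-snapshot death is
#' missing from the records.
#'
#' @param n_offspring Number of genotyped offspring (one phenotyped parent
#'   each).
#' @param n_variants Number of variants on the panel.
#' @param maf_spectrum Distribution of true alternate-allele frequencies.
#'   Either `list(dist = "uniform", min, max)` or
#'   `list(dist = "beta", shape1, shape2)`. Draws are clamped to
#'   \[0.001, 0.5\].
#' @param causal_effects `NULL`, or a data.frame with columns `variant`
#'   (1-based panel index), `trait` (one of `"paternal_lifespan"`,
#'   `"maternal_lifespan"`, `"age"`) and `beta` (years per allele on the
#'   *parental* allelic-dose scale; the expected offspring-regression slope is
#'   `beta / 2`).
#' @param total_phenotypic_variance Total variance of the trait in yr^2.
#' @param birth_year_range Integer vector `c(first, last)` of parental birth
#'   years.
#' @param snapshot_year Calendar year at which the database is frozen.
#' @param lifespan_window Admissible lifespan range in years; values outside
#'   are resampled, not clipped.
#' @param median_lifespan Named numeric, target median lifespan per trait
#'   (`paternal`, `maternal`).
#' @param missing_death_base_rate Probability that a death that did occur
#'   before the snapshot is nonetheless missing from the records.
#' @param genotype_missing_rate Per-entry genotype missingness probability.
#' @param n_subpops Number of discrete subpopulations (1 = panmictic).
#' @param fst Balding-Nichols differentiation parameter in \[0, 1).
#' @param chip_split Probability that an individual is typed on chip `"v2"`
#'   rather than `"v1"`.
#' @param seed Integer seed; every generator routine derives its stream from
#'   it, so identical configurations give identical outputs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_offspring = 100, n_variants = 10, seed = 1)
#' cfg$total_phenotypic_variance
#' @export
sim_config <- function(n_offspring,
                       n_variants,
                       maf_spectrum = list(dist = "uniform", min = 0.01, max = 0.5),
                       causal_effects = NULL,
                       total_phenotypic_variance = 166.2,
                       birth_year_range = c(1886L, 1940L),
                       snapshot_year = 2016L,
                       lifespan_window = c(40, 120),
                       median_lifespan = c(paternal = 76, maternal = 82),
                       missing_death_base_rate = 1 / 3,
                       genotype_missing_rate = 0,
                       n_subpops = 1L,
                       fst = 0,
                       chip_split = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_offspring = as.integer(n_offspring),
    n_variants = as.integer(n_variants),
    maf_spectrum = maf_spectrum,
    causal_effects = causal_effects,
    total_phenotypic_variance = total_phenotypic_variance,
    birth_year_range = as.integer(birth_year_range),
    snapshot_year = as.integer(snapshot_year),
    lifespan_window = as.numeric(lifespan_window),
    median_lifespan = median_lifespan,
    missing_death_base_rate = missing_death_base_rate,
    genotype_missing_rate = genotype_missing_rate,
    n_subpops = as.integer(n_subpops),
    fst = fst,
    chip_split = chip_split,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_offspring >= 1L, cfg$n_variants >= 1L)
  probs <- c(cfg$missing_death_base_rate, cfg$genotype_missing_rate, cfg$chip_split)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(cfg$total_phenotypic_variance) || cfg$total_phenotypic_variance <= 0) {
    stop("total_phenotypic_variance must be > 0", call. = FALSE)
  }
  if (length(cfg$lifespan_window) != 2L || diff(cfg$lifespan_window) <= 0) {
    stop("lifespan_window must be an ordered pair", call. = FALSE)
  }
  if (length(cfg$birth_year_range) != 2L || diff(cfg$birth_year_range) < 0) {
    stop("birth_year_range must be an ordered pair", call. = FALSE)
  }
  if (cfg$fst < 0 || cfg$fst >= 1) stop("fst must lie in [0, 1)", call. = FALSE)
  if (cfg$n_subpops < 1L) stop("n_subpops must be >= 1", call. = FALSE)
  if (!is.null(cfg$causal_effects)) {
    ce <- cfg$causal_effects
    need <- c("variant", "trait", "beta")
    if (!is.data.frame(ce) || !all(need %in% names(ce))) {
      stop("causal_effects must be a data.frame with columns variant, trait, beta",
           call. = FALSE)
    }
    if (any(ce$variant < 1L | ce$variant > cfg$n_variants)) {
      stop("causal variant index out of range", call. = FALSE)
    }
    ok_traits <- c("paternal_lifespan", "maternal_lifespan", "age")
    if (!all(ce$trait %in% ok_traits)) {
      stop("causal trait must be one of: ", paste(ok_traits, collapse = ", "),
           call. = FALSE)
    }
  }
  spec <- cfg$maf_spectrum
  if (!is.list(spec) || is.null(spec$dist) ||
      !spec$dist %in% c("uniform", "beta")) {
    stop("maf_spectrum must be list(dist = 'uniform'|'beta', ...)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  offspring: %d, variants: %d (maf spectrum: %s)\n",
              x$n_offspring, x$n_variants, x$maf_spectrum$dist))
  n_causal <- if (is.null(x$causal_effects)) 0L else nrow(x$causal_effects)
  cat(sprintf("  causal variants: %d; total phenotypic variance: %.1f yr^2\n",
              n_causal, x$total_phenotypic_variance))
  cat(sprintf("  birth cohorts %d-%d, snapshot %d, lifespan window [%g, %g]\n",
              x$birth_year_range[1], x$birth_year_range[2], x$snapshot_year,
              x$lifespan_window[1], x$lifespan_window[2]))
  cat(sprintf("  missing-death base rate %.3f, genotype missingness %.3f, chip split %.2f\n",
              x$missing_death_base_rate, x$genotype_missing_rate, x$chip_split))
  if (x$n_subpops > 1L) {
    cat(sprintf("  population structure: %d subpopulations, Fst = %.3f\n",
                x$n_subpops, x$fst))
  }
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Deterministic per-stage RNG streams: each generator seeds with
# config$seed + a fixed stage offset so the pipeline is reproducible
# stage by stage (kept < 2^31).
stage_seed <- function(cfg, stage) {
  offsets <- c(panel = 101L, parents = 211L, transmit = 307L,
               observe = 401L, relatedness = 503L)
  (cfg$seed %% 2000000000L) + offsets[[stage]]
}
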