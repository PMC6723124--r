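#' Draw unrelated genotypes at Hardy-Weinberg proportions
#'
#' Each dosage is an independent Binomial(2, p) draw, i.e. genotype classes
#' appear at the HWE proportions (1-p)^2, 2p(1-p), p^2 for the alternate
#' allele frequency p.
#'
#' @param n Number of individuals (rows).
#' @param freq Vector of alternate-allele frequencies, one per variant.
#' @return Integer dosage matrix `n x length(freq)` with values in 0:2.
#' @export
hwe_genotypes <- function(n, freq) {
  m <- length(freq)
  matrix(stats::rbinom(n * m, 2L, rep(freq, each = n)), nrow = n, ncol = m)
}

#' Mendelian gamete from a diploid dosage
#'
#' Transmits one allele per individual: always 0 from dosage 0, always 1 from
#' dosage 2, and a fair coin from heterozygotes.
#'
#' @param dosage Integer vector or matrix of dosages in 0:2.
#' @return Object of the same shape with transmitted allele counts in 0:1.
#' @export
mendelian_gamete <- function(dosage) {
  out <- stats::rbinom(length(dosage), 1L, as.vector(dosage) / 2)
  if (is.matrix(dosage)) dim(out) <- dim(dosage)
  out
}

#' Simulate the phenotyped parental generation
#'
#' Draws parental genotypes at Hardy-Weinberg proportions (per subpopulation
#' under the Balding-Nichols frequencies when structure is configured) and
#' builds the trait as an additive genetic value plus normal environmental
#' noise, with the environmental variance chosen so that the total phenotypic
#' variance equals `config$total_phenotypic_variance`. The phenotype is then
#' shifted to the configured sex-specific median and constrained to the
#' lifespan window by resampling the environmental term for out-of-window
#' individuals (never by clipping, which would pile mass on the boundaries).
#'
#' For the lifespan traits, `death_year = birth_year + lifespan` is kept on a
#' continuous (decimal-year) scale so the identity `lifespan = death_year -
#' birth_year` holds exactly. For the `"age"` trait the value is rounded to
#' whole years and `birth_year = snapshot_year - age`; death columns are NA
#' (these are the living genotyped individuals themselves).
#'
#' @param panel A `variant_panel` from [simulate_variant_panel()].
#' @param config A [sim_config()] object.
#' @param trait `"paternal_lifespan"`, `"maternal_lifespan"` or `"age"`.
#' @return A list with `genotypes` (parents x variants integer dosage matrix,
#'   with a `"subpop"` attribute) and `cohort` (a `cohort_table` data.frame
#'   with columns `iid`, `sex`, `birth_year`, `death_year`, `lifespan`,
#'   `age_at_snapshot`, `chip`, `offspring_iid`, `subpop`).
#' @export
simulate_parent_cohort <- function(panel, config,
                                   trait = c("paternal_lifespan",
                                             "maternal_lifespan", "age")) {
  trait <- match.arg(trait)
  validate_sim_config(config)
  set.seed(stage_seed(config, "parents"))
  n <- config$n_offspring
  m <- nrow(panel)
  beta <- panel[[paste0("beta_", trait)]]
  p <- panel$freq

  var_g <- sum(beta^2 * 2 * p * (1 - p))
  if (var_g >= config$total_phenotypic_variance) {
    stop("genetic variance (", signif(var_g, 4),
         ") meets or exceeds total phenotypic variance", call. = FALSE)
  }
  sd_e <- sqrt(config$total_phenotypic_variance - var_g)

  subpop_freq <- attr(panel, "subpop_freq")
  if (!is.null(subpop_freq)) {
    subpop <- sample.int(ncol(subpop_freq), n, replace = TRUE)
    geno <- matrix(0L, n, m)
    for (k in seq_len(ncol(subpop_freq))) {
      rows <- which(subpop == k)
      if (length(rows)) geno[rows, ] <- hwe_genotypes(length(rows), subpop_freq[, k])
    }
  } else {
    subpop <- rep.int(1L, n)
    geno <- hwe_genotypes(n, p)
  }

  gval <- if (any(beta != 0)) drop(geno %*% beta) else numeric(n)

  window <- if (trait == "age") {
    config$snapshot_year - rev(config$birth_year_range)
  } else {
    config$lifespan_window
  }
  target_median <- switch(trait,
    paternal_lifespan = config$median_lifespan[["paternal"]],
    maternal_lifespan = config$median_lifespan[["maternal"]],
    age = mean(config$snapshot_year - config$birth_year_range)
  )
  shift <- target_median - sum(beta * 2 * p)

  value <- gval + shift + stats::rnorm(n, 0, sd_e)
  if (trait == "age") value <- round(value)
  bad <- which(value < window[1] | value > window[2])
  iter <- 0L
  while (length(bad)) {
    value[bad] <- gval[bad] + shift + stats::rnorm(length(bad), 0, sd_e)
    if (trait == "age") value[bad] <- round(value[bad])
    bad <- bad[value[bad] < window[1] | value[bad] > window[2]]
    iter <- iter + 1L
    if (iter > 10000L) stop("lifespan window resampling failed to converge",
                            call. = FALSE)
  }

  if (trait == "age") {
    birth_year <- as.integer(config$snapshot_year - value)
    death_year <- rep(NA_real_, n)
    lifespan <- rep(NA_real_, n)
    sex <- sample(c("M", "F"), n, replace = TRUE)
  } else {
    birth_year <- sample(seq(config$birth_year_range[1],
                             config$birth_year_range[2]), n, replace = TRUE)
    lifespan <- value
    death_year <- birth_year + lifespan
    sex <- if (trait == "paternal_lifespan") rep("M", n) else rep("F", n)
  }

  iid <- sprintf("P%06d", seq_len(n))
  cohort <- data.frame(
    iid = iid,
    sex = sex,
    birth_year = birth_year,
    death_year = death_year,
    lifespan = lifespan,
    age_at_snapshot = config$snapshot_year - birth_year,
    chip = NA_character_,
    offspring_iid = sprintf("O%06d", seq_len(n)),
    subpop = subpop,
    stringsAsFactors = FALSE
  )
  class(cohort) <- c("cohort_table", "data.frame")
  rownames(geno) <- iid
  colnames(geno) <- panel$variant
  attr(geno, "subpop") <- subpop
  list(genotypes = geno, cohort = cohort)
}

#' Transmit alleles from phenotyped parents to genotyped offspring
#'
#' Each offspring receives one allele sampled uniformly from the phenotyped
#' parent's two alleles (perfect Mendelian segregation) and one allele from a
#' random mate drawn from the population at Hardy-Weinberg proportions. The
#' mate is never phenotyped. When the panel carries subpopulation
#' frequencies, the mate is drawn from the parent's own subpopulation.
#'
#' The parent-offspring dosage correlation implied by this rule is 1/2
#' (cov = pq against variance 2pq), which is what dilutes parental-scale
#' effects by half in offspring-genotype regressions.
#'
#' @param parent_genotypes Parent dosage matrix from
#'   [simulate_parent_cohort()].
#' @param panel The matching `variant_panel`.
#' @param config The [sim_config()] used throughout.
#' @return Integer offspring dosage matrix with the same dimensions, rows
#'   named by offspring id.
#' @export
transmit_offspring <- function(parent_genotypes, panel, config) {
  if (ncol(parent_genotypes) != nrow(panel)) {
    stop("genotype/panel dimension mismatch", call. = FALSE)
  }
  set.seed(stage_seed(config, "transmit"))
  n <- nrow(parent_genotypes)
  m <- nrow(panel)

  from_parent <- mendelian_gamete(parent_genotypes)

  subpop_freq <- attr(panel, "subpop_freq")
  subpop <- attr(parent_genotypes, "subpop")
  if (!is.null(subpop_freq) && !is.null(subpop)) {
    mate <- matrix(0L, n, m)
    for (k in seq_len(ncol(subpop_freq))) {
      rows <- which(subpop == k)
      if (length(rows)) mate[rows, ] <- hwe_genotypes(length(rows), subpop_freq[, k])
    }
  } else {
    mate <- hwe_genotypes(n, panel$freq)
  }
  from_mate <- mendelian_gamete(mate)

  off <- from_parent + from_mate
  rownames(off) <- sprintf("O%06d", seq_len(n))
  colnames(off) <- panel$variant
  attr(off, "subpop") <- subpop
  off
}

#' Apply the snapshot observation model
#'
#' Replays how the database sees the true cohort at `snapshot_year`:
#' \itemize{
#'   \item individuals whose death falls after the snapshot are alive and
#'     genuinely right-censored, so their `death_year` (and `lifespan`)
#'     become NA;
#'   \item among deaths that did occur before the snapshot, the death record
#'     is independently missing with probability
#'     `missing_death_base_rate`, regardless of lifespan -- these are
#'     indistinguishable from the censored;
#'   \item genotype entries are set missing at `genotype_missing_rate`;
#'   \item a chip version (`"v1"`/`"v2"`) is assigned by `chip_split`.
#' }
#' Lifespan values of individuals that remain observed are never altered --
#' the model changes observability only.
#'
#' @param cohort A `cohort_table`.
#' @param config The [sim_config()].
#' @param genotypes Optional dosage matrix to receive missingness.
#' @return When `genotypes` is NULL, the masked `cohort_table`; otherwise
#'   `list(cohort, genotypes)`.
#' @export
apply_observation_model <- function(cohort, config, genotypes = NULL) {
  set.seed(stage_seed(config, "observe"))
  n <- nrow(cohort)
  out <- cohort

  alive <- !is.na(out$death_year) & out$death_year > config$snapshot_year
  dead_observed <- !is.na(out$death_year) & !alive
  lost <- dead_observed & stats::runif(n) < config$missing_death_base_rate
  hide <- alive | lost
  out$death_year[hide] <- NA_real_
  out$lifespan[hide] <- NA_real_

  out$chip <- ifelse(stats::runif(n) < config$chip_split, "v2", "v1")

  if (is.null(genotypes)) return(out)

  if (config$genotype_missing_rate > 0) {
    miss <- stats::runif(length(genotypes)) < config$genotype_missing_rate
    genotypes[miss] <- NA_integer_
  }
  list(cohort = out, genotypes = genotypes)
}

#' Simulate a pairwise relatedness table in centimorgans
#'
#' Emits the abstract relatedness scores the sample-pruning step consumes:
#' unrelated background pairs share little identity-by-descent, while
#' designated close pairs (parent-offspring or full siblings) share half of a
#' 3545-cM autosomal map, i.e. about 1772 cM.
#'
#' @param ids Character vector of individual ids.
#' @param n_related_pairs Number of disjoint close pairs to plant.
#' @param related_cm IBD sharing of planted pairs (cM).
#' @param background_mean_cm Mean of the exponential background sharing (cM).
#' @param seed Integer seed.
#' @return A data.frame `id1`, `id2`, `cm` over all unordered pairs.
#' @export
simulate_relatedness <- function(ids, n_related_pairs = 0L,
                                 related_cm = 1772, background_mean_cm = 30,
                                 seed = 1L) {
  set.seed(seed)
  n <- length(ids)
  if (n < 2L) stop("need at least two individuals", call. = FALSE)
  pr <- utils::combn(n, 2L)
  cm <- pmin(stats::rexp(ncol(pr), 1 / background_mean_cm), 250)
  tab <- data.frame(id1 = ids[pr[1, ]], id2 = ids[pr[2, ]], cm = cm,
                    stringsAsFactors = FALSE)
  if (n_related_pairs > 0L) {
    if (2L * n_related_pairs > n) stop("too many related pairs requested",
                                       call. = FALSE)
    picked <- sample.int(n, 2L * n_related_pairs)
    for (j in seq_len(n_related_pairs)) {
      a <- picked[2L * j - 1L]; b <- picked[2L * j]
      hit <- (tab$id1 == ids[min(a, b)] & tab$id2 == ids[max(a, b)])
      tab$cm[hit] <- related_cm
    }
  }
  tab
}
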