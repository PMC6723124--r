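#' Simulate a variant panel
#'
#' Draws true alternate-allele frequencies from the configured spectrum
#' (clamped to \[0.001, 0.5\]), lays variants out on a genome with strictly
#' increasing physical and genetic positions within chromosomes, and assigns
#' the configured additive effects (years per allele, parental scale).
#'
#' Genetic position is taken as 1 cM per Mb, the genome-wide average
#' recombination rate, which is what downstream LD-score windows use.
#' With `n_subpops > 1`, per-subpopulation frequencies are drawn from the
#' Balding-Nichols model, `p_k ~ Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`,
#' and stored in the `"subpop_freq"` attribute.
#'
#' @param config A [sim_config()] object.
#' @return A data.frame of class `variant_panel` with columns `variant`,
#'   `chrom`, `pos`, `cm`, `ref`, `alt`, `freq`, and one `beta_*` column per
#'   trait.
#' @examples
#' panel <- simulate_variant_panel(sim_config(100, 20, seed = 7))
#' range(panel$freq)
#' @export
simulate_variant_panel <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config, "panel"))
  m <- config$n_variants

  freq <- draw_maf(config$maf_spectrum, m)
  freq <- pmin(pmax(freq, 0.001), 0.5)

  # spread variants over up to 22 chromosomes, positions increasing within each
  n_chr <- min(22L, m)
  chrom <- sort(rep_len(seq_len(n_chr), m))
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- cumsum(sample(1e4:2e5, length(idx), replace = TRUE))
  }
  cm <- pos / 1e6  # 1 cM per Mb

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))

  panel <- data.frame(
    variant = sprintf("snp%05d", seq_len(m)),
    chrom = chrom,
    pos = pos,
    cm = cm,
    ref = ref,
    alt = alt,
    freq = freq,
    beta_paternal_lifespan = 0,
    beta_maternal_lifespan = 0,
    beta_age = 0,
    stringsAsFactors = FALSE,
    row.names = NULL
  )

  if (!is.null(config$causal_effects)) {
    ce <- config$causal_effects
    for (i in seq_len(nrow(ce))) {
      col <- paste0("beta_", ce$trait[i])
      panel[[col]][ce$variant[i]] <- ce$beta[i]
      if (!is.null(ce$freq) && !is.na(ce$freq[i])) {
        panel$freq[ce$variant[i]] <- ce$freq[i]
      }
    }
  }

  if (config$n_subpops > 1L && config$fst > 0) {
    f <- config$fst
    a <- panel$freq * (1 - f) / f
    b <- (1 - panel$freq) * (1 - f) / f
    sub <- vapply(seq_len(config$n_subpops), function(k) {
      pmin(pmax(stats::rbeta(m, a, b), 1e-4), 1 - 1e-4)
    }, numeric(m))
    attr(panel, "subpop_freq") <- sub
  }

  class(panel) <- c("variant_panel", "data.frame")
  panel
}

draw_maf <- function(spec, m) {
  switch(spec$dist,
    uniform = stats::runif(m, spec$min %||% 0.001, spec$max %||% 0.5),
    beta = stats::rbeta(m, spec$shape1, spec$shape2),
    stop("unknown maf_spectrum dist: ", spec$dist, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
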