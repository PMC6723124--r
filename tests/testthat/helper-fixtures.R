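# Small reusable fixtures, all generated in code.

# a single-causal-variant configuration on a short panel
one_locus_config <- function(n = 1000L, beta = 0.75, freq = 0.2,
                             trait = "paternal_lifespan", seed = 1L, ...) {
  sim_config(
    n_offspring = n, n_variants = 5L,
    causal_effects = data.frame(variant = 1L, trait = trait,
                                beta = beta, freq = freq),
    seed = seed, ...
  )
}

# dosage matrix with exact genotype counts (n0, n1, n2) per column
counted_genotypes <- function(counts, n_missing = 0L) {
  cols <- lapply(seq_len(nrow(counts)), function(j) {
    g <- rep(0:2, times = counts[j, ])
    if (n_missing > 0L) g <- c(g, rep(NA_integer_, n_missing))
    g
  })
  g <- do.call(cbind, cols)
  colnames(g) <- sprintf("v%05d", seq_len(ncol(g)))
  g
}

# minimal summary-statistic table builder
make_sumstats <- function(variant, ea, oa, z, n, eaf, chr = 1L, pos = NULL) {
  if (is.null(pos)) pos <- seq_along(variant) * 1000L
  as_study_summary(data.frame(
    variant = variant, chr = chr, pos = pos, ea = ea, oa = oa,
    z = z, n = n, eaf = eaf, stringsAsFactors = FALSE
  ))
}

# a panel data.frame built by hand (bypasses the simulator)
manual_panel <- function(m, cm, chrom = 1L, freq = 0.3) {
  data.frame(
    variant = sprintf("snp%05d", seq_len(m)),
    chrom = rep_len(chrom, m),
    pos = round(cm * 1e6),
    cm = cm,
    ref = "A", alt = "G",
    freq = rep_len(freq, m),
    beta_paternal_lifespan = 0, beta_maternal_lifespan = 0, beta_age = 0,
    stringsAsFactors = FALSE
  )
}
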