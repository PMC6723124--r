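Package: proxygwas
Title: Proxy-Phenotype Lifespan GWAS: Simulation, Power, Association and Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide association studies of parental lifespan
    measured through genotyped offspring (the proxy-phenotype, or kin-cohort,
    design). Provides a synthetic cohort generator with the design's
    observation model (birth cohorts, right-censorship at a data snapshot,
    missing death records, genotyping-chip versions), Mendelian-transmission
    power simulation with effect-dilution rescaling to the parental allelic
    dose, right-censorship estimation from a fully observed baseline birth
    cohort, PLINK-style variant and sample quality control with LD pruning and
    principal-component covariates, a single-variant association engine with
    genomic control for quantitative and age-tail case/control traits,
    birth-cohort-sliced effect estimates and allele-frequency-by-lifespan
    grids, a minimal LD-score regression stage for SNP heritability and
    genetic correlation with constrained intercepts, and sample-size-weighted
    z-score meta-analysis of two summary-statistic sets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
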