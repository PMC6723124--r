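---
title: "Proxy-phenotype lifespan GWAS: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proxy-phenotype lifespan GWAS: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxygwas)
```

## The design

Large consumer-genomics cohorts contain genotyped customers whose *parents'*
lifespans are recorded in linked genealogies, while the parents themselves
are rarely genotyped. The proxy-phenotype (kin-cohort) design therefore
regresses the parental phenotype on the *offspring's* allele dosage. Under
random mating and Mendelian segregation the parent-offspring dosage
covariance at a biallelic locus with allele frequency $p$ is $pq$, against a
dosage variance of $2pq$, so the regression recovers only half of the true
parental-scale effect:

$$E[\hat\beta_{\text{offspring}}] = \tfrac{1}{2}\,\beta_{\text{parental}}.$$

Downstream, effect sizes and their standard errors are doubled
(`rescale_parental()`), and per-SNP variance explained (and SNP
heritability) quadrupled, to express results on the parental allelic dose.
The rescaling is guarded by a scale flag so it can only be applied once; z
and P are unchanged by it.

## What the synthetic cohort emulates

`sim_config()` fixes the study conditions; the defaults are the conditions
the rest of the package assumes, chosen once:

* **Genetics.** Biallelic variants at Hardy–Weinberg proportions; allele
  frequencies from a configurable spectrum clamped to [0.001, 0.5];
  additive effects in years per allele on the parental scale. Optional
  discrete population structure uses the Balding–Nichols model
  ($p_k \sim \mathrm{Beta}(p\frac{1-F}{F}, q\frac{1-F}{F})$); the structure
  model is this package's choice, as the design only requires *some*
  differentiated subpopulations for the PCA stage to detect.
* **Phenotype.** Lifespan is an additive genetic value plus normal
  environmental noise, with total phenotypic variance defaulting to
  166.2 yr² (a paternal-lifespan phenotypic variance typical of early
  20th-century birth cohorts) and sex-specific medians of 76 (paternal) and
  82 (maternal) years. Lifespans are restricted to [40, 120] years by
  *resampling* the environmental term for out-of-window individuals;
  clipping would create probability atoms at the boundaries that distort
  both the variance and the censorship baseline.
* **Demography.** Birth years uniform over 1886–1940, observed at a 2016
  snapshot. `death_year = birth_year + lifespan` is kept on a continuous
  (decimal-year) scale so the identity between lifespan and the year
  difference is exact and the lifespan distribution carries no integer
  atoms; this matters for the censorship estimator, whose baseline CDF is
  evaluated strictly below the observable maximum.
* **Observation model.** Deaths after the snapshot are genuinely
  right-censored (record erased); among deaths before the snapshot, records
  are *additionally* lost at a base rate of 1/3, independent of lifespan —
  the two are indistinguishable in the data, which is exactly the ambiguity
  the design must handle. Genotype calls go missing at a configurable rate
  and each individual is assigned one of two chip versions. The observation
  model never alters a lifespan value, only its observability.
* **Pedigree.** Exactly one phenotyped parent per genotyped offspring; the
  mate is drawn fresh from the population and never phenotyped, mirroring
  the single-parent regression. Deeper pedigrees and assortative mating are
  out of scope. For the relatedness-pruning stage, which consumes abstract
  pairwise IBD scores in cM, `simulate_relatedness()` plants close pairs at
  1772 cM (half of a 3545-cM autosomal map) on an exponential background.

The `"age"` trait treats the genotyped individuals themselves as the study
subjects (everyone alive at the snapshot), with age = snapshot year − birth
year.

What the generator does **not** emulate: linkage disequilibrium between
variants is only what sampling noise and shared population structure induce
(except where tests construct correlated blocks explicitly), there is no
genotyping error, no imputation uncertainty, and record loss is independent
of lifespan. Passing tests therefore demonstrate correctness of the
*methods* under the stated model, not robustness to every artefact of real
array data.

## Power analysis

`power_replicate()` implements one draw of the design's power simulation:
HWE parents, normal environment, Mendelian transmission with a random mate,
then a single-SNP regression of the parental phenotype on offspring dosage.
The phenotype here is deliberately plain normal (no window truncation):
power is a property of the regression, and the analytic check below assumes
normality. `power_grid()` crosses frequency, effect and cohort size, with
fresh parents every replicate, 50 replicates per cell by default, and the
genome-wide threshold $\alpha = 5\times 10^{-8}$.

The closed-form check is the non-centrality approximation

$$\mathrm{NCP} = N\,(\beta/2)^2\,2pq/\sigma^2, \qquad
\text{power} \approx P(\chi^2_1(\mathrm{NCP}) > \chi^2_{1,\alpha}).$$

At $p = 0.2$, $\beta = 0.75$ yr, $N = 170{,}000$, $\sigma^2 = 166.2$ yr²
this gives NCP ≈ 46 and power ≈ 0.91, which is why 166.2 yr² is the
package's default total variance: it makes the Monte-Carlo grid, the
analytic approximation and the headline design claim (power 0.90 at those
settings) mutually consistent. Effect sizes in the grid are interpreted on
the parental scale; the 0.90-power consistency check above is what pins
that interpretation down.

## Censorship estimation

For birth year $y$ observed at snapshot $S$, only lifespans below
$c_y = S - y$ are observable. Using a baseline cohort old enough to be
essentially fully observed (default 1886–1910 at a 2016 snapshot), with
pooled lifespan CDF $F$ taken as $F(c) = P(L < c)$, the still-alive count
in year $y$ is estimated by odds-inflating the observed complete count:

$$\widehat{\text{alive}}(y) = n_{\text{complete}}(y)\,
\frac{1 - F(c_y)}{F(c_y)},$$

with annual assumed-censored fraction
$\widehat{\text{alive}}/(\widehat{\text{alive}} + n_{\text{complete}})$ and
a complete-count-weighted cumulative aggregate. Two properties are worth
noting. First, the annual *fraction* is algebraically invariant to a
lifespan-independent record-loss rate (the loss scales
$n_{\text{complete}}$ and $\widehat{\text{alive}}$ equally), so the
estimator is untroubled by the 1/3 base loss; recovery tests nevertheless
switch that rate off so the generator's true alive fraction is directly
comparable. Second, the baseline itself carries a small amount of true
censorship (its youngest members can only be observed to age ~106), which
biases the estimated fractions down by about the baseline's upper-tail
mass (~1%); the recovery tests allow for this explicitly. Years with
$c_y \ge 120$ return 0; a baseline with no mass below $c_y$ is flagged
undefined rather than guessed. The odds-inflation formula is one
reconstruction of the baseline principle and is exposed behind the named
`estimate_censorship()` interface so alternative estimators can be slotted
in.

## Quality control

Defaults follow array-GWAS convention: folded MAF ≥ 0.5% (inclusive),
variant missingness ≤ 20%, individual missingness ≤ 2%, and removal of the
worst 1% of variants by Hardy–Weinberg $\chi^2$ (goodness of fit against
$\hat p^2, 2\hat p\hat q, \hat q^2$; the test statistic is this package's
choice). The filter order is fixed — variant missingness → MAF → HWE rank →
individual missingness → LD pruning — because order changes the HWE
removal set; note the rank-based HWE step is inherently one-shot (running
it again on its own output removes a further 1%), unlike the threshold
filters, which are idempotent.

LD pruning is greedy within sliding windows (50 variants, step 5 — common
convention, configurable): the highest-r² offending pair is processed
first (ties by lowest column index pair) and its lower-MAF member removed
(exact MAF tie: the higher column index). PCA covariates follow the usual
recipe: prune to near-linkage-equilibrium (r² < 0.2), subsample SNPs,
standardize by $\sqrt{2\hat p\hat q}$, mean-impute missing entries after
centering, exact SVD. Relative pruning repeatedly removes one random
member (seeded) of the most-related pair above 300 cM; an individual in no
offending pair is never touched.

## Association engine

`assoc_quant()` is per-variant OLS with complete-case handling of missing
genotypes (no dosage imputation — the package's choice, stated rather than
assumed). Fully observed variants run through a Frisch–Waugh
residualization fast path that is algebraically exact OLS; partially
missing variants fall back to per-variant QR. Two-sided P values use the
normal approximation to $\beta/\mathrm{SE}$; at the sample sizes this
design targets the difference from the t reference is far below any
reported digit. `assoc_case_control()` takes cases above the upper 5%
age quantile and controls at or below the median age (e.g. tails of 86/87
years against medians of 65/64 in a sex-stratified consumer cohort), with
the gap excluded, and flags (never crashes on) separation.

Genomic control uses $\lambda = \mathrm{median}(\chi^2)/0.455936$ and
divides statistics by $\max(\lambda, 1)$: deflation is not applied, the
usual conservative convention. Permutation of the phenotype vector against
a null genotype matrix centers $\lambda$ at 1.00, which is the package's
calibration check that the non-normal, window-truncated lifespan
distribution does not itself inflate the scan.

Cohort-sliced effects rerun the scan inside eleven fixed 4–8-year
birth-year windows (1886–1894 through 1935–1940, consecutive windows
sharing a boundary year, the last pair overlapping by one year — the slice
list is kept verbatim rather than regularized). The allele-frequency grid
bins parents by (birth cohort × lifespan class) and masks cells under 500
individuals by default, the occupancy floor used for such displays.

## LD-score regression stage

LD scores sum adjusted squared correlations,
$r^2_{\text{adj}} = r^2 - (1 - r^2)/(n_{\text{ref}} - 2)$, over ±1 cM
windows (genetic positions at 1 cM/Mb in the generator). Heritability is
the slope of a weighted regression of $\chi^2$ on $N\ell/M$ with weights
$1/\max(\ell, 1)$ — a deliberate simplification of the reference
implementation's full heteroskedasticity weighting, adequate for the
moderately polygenic, modest-$h^2$ regime this package simulates. Standard
errors come from a delete-a-block jackknife over 200 contiguous blocks.
Genetic correlation regresses $z_1 z_2$ on $\sqrt{N_1 N_2}\,\ell/M$; when
constrained, per-trait intercepts are fixed at 1 and the covariance
intercept at $r_p N_{12}/\sqrt{N_1 N_2}$ (which collapses to $r_p$ at full
overlap and to 0 at none). Estimates are reported raw; $|r_g| > 1.25$
warns, never truncates. Parental-dose rescaling of $h^2$ (×4) happens
downstream of this module, once.

Recovery tests simulate summary statistics at the z-score level
($z_j \sim N(0,\, 1 + N h^2 \ell_j/M)$, with the matching bivariate
covariance for two traits). This is the generative model the regression
fits, so it isolates the estimator from the separate question of whether a
small simulated genotype panel can produce realistic LD; genotype-level LD
scores are exercised by their own unit tests.

## Meta-analysis

Two summary-statistic sets are intersected on variant id; swapped
effect/other alleles flip the sign of one study's z; other allele
combinations are dropped. Strand-ambiguous variants (A/T, C/G) are dropped
when study frequencies match the flipped orientation better than the
direct one — the frequency comparison cannot then resolve strand. Variants
below 0.5% folded MAF in either study are removed. Combination is the
METAL-style sample-size scheme: per-study z deflated by
$\sqrt{\max(\lambda, 1)}$, then
$z_{\text{meta}} = (\sqrt{N_a}\,z_a + \sqrt{N_b}\,z_b)/\sqrt{N_a + N_b}$,
with genome-wide significance at $5\times10^{-8}$. Effect sizes are not
meta-analyzed; β/SE inputs are converted to z on read.

## Problem sizes and tolerances in the test suite

The suite generates everything at run time. The sizes are the package's
own choices, large enough that every stochastic check sits well inside its
stated band: HWE goodness-of-fit at 50,000 parents; transmission
correlation on 100,000 pairs (±0.01); dilution via 300 single-locus
replicates at N = 30,000 across a frequency grid (±0.02); permutation λ on
a 10,000 × 5,000 null cohort, 20 permutations (mean ±0.02); power at the
headline cell with 200 replicates (±0.05, Monte-Carlo); LDSC recovery at
M = 4,000–5,000 with 2-jackknife-SE bands; the association engine against
a per-variant least-squares oracle at 1e-8 relative tolerance. Exact
identities (Bonferroni threshold, Stouffer self-meta √2 scaling,
constrained intercepts, GT encodings, rescaling factors) are tested
exactly.

## Known limitations

* No phasing, imputation, or reference-panel LD: the LD structure available
  to `compute_ld_scores()` is whatever the genotype matrix carries.
* Record loss is modeled independent of lifespan; differential
  genealogy completeness by longevity is not represented.
* The case/control engine uses plain logistic regression; no saddlepoint or
  Firth correction for extreme case/control imbalance at rare variants.
* Population structure is discrete (island model); admixture clines are not
  generated.
* Survival-model alternatives (e.g. Cox proportional hazards) are
  deliberately out of scope: with a third of death records missing
  non-randomly, the hazard framework's censoring assumptions do not hold,
  which is the very motivation for the windowed-lifespan + censorship
  analysis implemented here.
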