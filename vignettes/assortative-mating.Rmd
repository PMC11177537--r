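---
title: "Assortative mating and the genetic structure it induces: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assortative mating and the genetic structure it induces: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Positive assortative mating (AM) — mate choice based on phenotypic or
ancestral similarity — leaves two signatures in genotype data beyond the
spousal correlation itself: an intra-locus correlation (heterozygote
deficit, Wright's F) and an inter-locus correlation (long-range linkage
disequilibrium between unlinked markers, even across chromosomes).
`amstruct` implements the full analysis chain used to quantify these
signatures in family-based cohorts — quality control, reference-anchored
ancestry PCA, polygenic scoring with the polygenic transmission
disequilibrium test (pTDT), spousal-correlation statistics, and a
resampling comparison of cross-chromosome D² between ancestry-informative
and less informative SNPs — together with a forward simulator so that
every stage can be exercised and calibrated without access-restricted
cohort data.

# Statistics implemented

**Wright's F.** For a bi-allelic marker with observed heterozygote count
$n_{oAa}$ and Hardy–Weinberg expectation $n_{eAa} = 2\hat p(1-\hat p)n$,

$$F = 1 - n_{oAa}/n_{eAa}.$$

$F$ is undefined at monomorphic markers; such markers are excluded from
set means with a recorded contribution count, never imputed.  Pooling
subpopulations with frequencies $p_1, p_2$ in equal proportions gives the
Wahlund expectation $F = (p_1-p_2)^2 / (4\bar p\bar q)$, which the test
suite verifies against simulation.

**Two-locus D².** With haplotype frequency $p_{AB}$ and allele
frequencies $p_A$, $p_B$,

$$D^2 = (p_{AB} - p_A p_B)^2,$$

invariant to allele relabelling at either locus.  Haplotype frequencies
are estimated from unphased genotypes by EM: only the double
heterozygote is phase-ambiguous, and the E-step assigns it coupling
weight $p_{AB}p_{ab}/(p_{AB}p_{ab}+p_{Ab}p_{aB})$.  Frequencies start at
linkage equilibrium and iterate until the largest frequency change is
below 1e-10 (cap 1000 iterations; non-convergence is flagged, the pair
retained).  The M-step preserves the observed allele counts, so the
fitted margins always equal the genotype-derived allele frequencies.
The user-facing estimator is pure R; the resampling engine calls an
equivalent C++ kernel (tested for exact agreement) because a single
comparison involves on the order of a million pairwise EM fits.

**The resampling design.** From an LD-pruned panel (r² > 0.1 removed in
500-kb windows, greedy left-to-right), each iteration randomly thins to
markers ≥ 500 kb apart (seeded visiting order; per-iteration seed =
base seed + iteration, recorded), ranks the thinned set by |PC1|
loading, and takes the top-K and bottom-K markers (K defaults to 200;
1000 is the larger preset).  Per pedigree role the iteration records the
mean F over each set and the mean D² over all different-chromosome
pairs within each set; same-chromosome pairs are excluded entirely.
Top and bottom iteration means are compared with Welch's two-sample
t-test per role and statistic.  The iteration means share samples (only
the SNP thinning is resampled); the t-test treats them as independent,
as in the design this reimplements — the output carries that caveat.

**pTDT.** Per trio, the deviation is
$(\text{child} - \text{midparent})/\mathrm{sd}(\text{midparent})$, with
the sample (n−1) standard deviation of midparent scores across included
trios, and a one-sample two-sided t-test on the mean deviation.  When
every child equals its midparent the deviation is identically zero and
the statistic is defined as t = 0, p = 1.

**Odd/even-chromosome assortment (θ).** Polygenic scores are computed
separately from odd- and even-chromosome variants (disjoint sets),
standardized, and regressed on one another with the top 20 principal
components of the LD-pruned (r² > 0.1, 1-Mb window) opposite-parity
panel as covariates:
$S_o = \theta S_e + PCE_{1..20}$ and $S_e = \theta S_o + PCO_{1..20}$.
Both estimates are reported, plus their inverse-variance-weighted mean.
Standardizing the scores puts θ on the correlation scale; the PC
covariates absorb ancestry-driven correlation, so θ isolates
score-based assortment.

**Spousal correlations and comparisons.** Quantitative-trait spousal
correlations use Spearman's coefficient (exact p for n ≤ 10, t
approximation otherwise); ancestry PCs and polygenic scores use
Pearson's.  Confidence intervals use the Fisher z transform (labelled
approximate for Spearman).  Independent strata are compared with
Fisher's z test,
$z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2)/
\sqrt{1/(n_1-3) + 1/(n_2-3)}$.  Subgroups are analysed only when they
reach the power rule $n \ge \lceil ((z_{1-\alpha/2}+z_{\text{power}})/
\operatorname{atanh} r)^2 + 3\rceil$, which gives n = 85 for 80% power
at r = 0.3 and α = 0.05.  Bonferroni correction divides α by the
configured family size (336 in the design this follows; the enumeration
of that family is taken as configuration, not re-derived).

**PGS scoring.** Weights are consumed as given (typically shrunk by an
external method; shrinkage itself is out of scope).  The
summary-statistic retention filter removes SNPs with
SD_ss < 0.5·SD_test, SD_ss > 0.1 + SD_test, SD_ss < 0.1, or
SD_test < 0.05, where SD_ss = 2/(se·√n_eff) with
n_eff = 4/(1/n_case + 1/n_control) for binary traits,
SD_ss = 1/(se·√n) for quantitative traits, and
SD_test = √(2·AF·(1−AF)) with AF the founder allele frequency.  Missing
genotypes are imputed with the founder mean dosage; scores are
standardized over founders and optionally residualized on age, sex and
ten PCs.

# Quality control

Filters run in a fixed order: sample missingness (> 5% removed, strict
inequality), variant call rate (≥ 95% kept), extended-LD region
exclusion (BED, 0-based half-open: a 1-based position p is inside
(start, end] iff start < p ≤ end), minor allele frequency (< 0.01
removed), Hardy–Weinberg exact test (p < 1e-5 removed), Mendelian error
rate (> 5% removed).  MAF and HWE are computed on founders only:
offspring duplicate parental chromosomes and would distort both.  The
HWE test is the plain two-sided exact test (probabilities of
heterozygote counts no more likely than observed, conditional on allele
counts), with no mid-p correction, matching common genotype-QC tooling.
Genotypes at Mendelian-inconsistent cells are left in place — the filter
removes variants, not calls.  Variants with no informative trio keep an
undefined error rate and are retained with a flag.

# The simulator

`simulate_cohort()` generates quartet families from an admixed
population: two ancestral subpopulations diverge under the
Balding–Nichols model (subpopulation frequencies Beta-distributed
around an ancestral frequency drawn uniform on [0.05, 0.95],
parameterized by FST), founders carry a continuous admixture proportion
α ~ Beta(b, b), and a founder's genotype at each marker is binomial
with frequency αp₁ + (1−α)p₂.  Mate assignment is a Gaussian-copula
coupling on ancestry ranks (and trait ranks when trait assortment is
configured; with both active, a weighted latent calibrates each
marginal correlation approximately).  Transmission is Mendelian with
unlinked loci.

Key defaults and why:

* `fst = 0.005` — a within-continent divergence scale.  No quantitative
  within-European value is established; this is a configuration choice
  exposed to the user, not a claim.  Analyses that need a clearly
  resolvable ancestry axis at desk scale (e.g. the D² comparison at
  2,000 SNPs) use 0.01–0.1 explicitly.
* `admixture_beta = 2` — a broad, unimodal α distribution
  (variance 0.05).  `Inf` gives the panmictic limit (all α = 0.5),
  the structureless null world.
* `rho_ancestry = 0.5` — the central ancestry-assortment condition
  studied; `rho_trait` defaults to 0.
* `h2 = 0.5`, `n_causal = 100` — a polygenic trait of moderate
  heritability.  Causal effects are normal draws rescaled so the
  genetic variance over the parent generation is exactly h²; the trait
  (liability) adds normal noise of variance 1 − h².
* `ascertainment_quantile = 0.02` — a 2% liability-threshold
  prevalence.  A child is affected iff its liability exceeds the
  (1 − q) empirical quantile of the parent generation; families with
  exactly one affected child form the simplex-like subset.
* `n_generations = 2` — see below.

**Why two generations.**  Within a single generation, who marries whom
cannot change the genotypic structure of the parents themselves: the
set of fathers is the same under any pairing.  Assortment leaves its
intra- and inter-locus signature on a generation only through that
generation's *ancestors*.  With `n_generations = 2` the configured
mating rule acts in the grandparental generation as well, so parental
F and D² respond to the assortment parameter, and the offspring
generation shows the attenuation expected from progressive intermixing
(offspring ancestry variance is (1+ρ)/2 times the parental one) — both
patterns the test suite checks.

**Group labels** for the two severity strata are an independent
per-family coin flip — exchangeable by construction, so the Fisher-z
comparison's type-I error is testable against a true null.  Carrier
flags are emitted but always FALSE: rare-variant carrier status is an
input in real analyses, not something this generator models.

**Reference panels** are drawn at the two ancestral poles (α = 1, 0)
plus three intermediate labelled subpanels (α = 0.65, 0.5, 0.35).  The
poles act as the continental-scale contrast panels for the round-1
inclusion rule; the intermediates as the retained-ancestry subpanels
for the round-2 PCA whose loadings feed all downstream analyses.

**What the generator does not emulate:** linkage and recombination
(irrelevant for markers ≥ 500 kb apart and cross-chromosome pairs,
where assortment-induced LD does not require linkage), X-linked
variation, genotyping-platform artefacts, geographic stratification,
de novo variation, and multi-generation approach to AM equilibrium.
Passing tests therefore demonstrate correctness of the estimators and
the qualitative signatures of AM under this model, not cohort-specific
magnitudes.

# Ancestry module decisions

The PCA is fitted jointly on cohort founders plus the reference panel,
with per-variant standardization to mean 2p̂ and scale √(2p̂(1−p̂))
(p̂ from the fitting set); children are projected with the fitted
standardization and loadings rather than refitted, so sibling/parent
duplication cannot distort the axes.  Loadings columns are unit-norm
with the largest-magnitude entry forced positive, making ranked SNP
lists reproducible across eigensolvers.  The inclusion rule is applied
per individual — a sample is assigned to the target ancestry iff on PC1
*and* PC2 its distance to the target centroid is strictly smaller than
to every contrast centroid (ties exclude) — and a family is retained
only if every genotyped member passes.  Ancestry-informativeness is
ranked by |PC1| *loading* (the per-variant quantity; per-component
eigenvalues are scalars and cannot rank SNPs), ties broken by genomic
coordinate.

# Numerical and design choices

* EM tolerance 1e-10 on frequencies, 1000-iteration cap; degenerate
  (monomorphic) pairs return the equilibrium solution with D = 0.
* The HWE exact test uses the two-way probability recurrence anchored
  at the conditional mode, so large samples cannot overflow.
* Spousal correlations use pairwise-complete deletion per variable;
  regression models use listwise deletion within each model.
* Education enters regressions as ordered integer levels; the coding
  is configurable input.
* sd(midparent) in the pTDT uses the n−1 sample standard deviation.
* θ estimates are combined by inverse-variance weighting; both raw
  regressions are always reported.
* Per-iteration thinning seeds are base seed + iteration index, making
  every stochastic stage reproducible from one run seed.
* Strand is never flipped; palindromic (A/T, C/G) variants are dropped
  during summary-statistic harmonization with a logged count.
* Missingness is encoded as NA, never as a zero dosage; PLINK 2-bit
  codes are decoded through a 256×4 lookup table and round-trip
  bit-exactly.
* Duplicate (chromosome, position) records and non-autosomal variants
  are dropped at load with logged counts; duplicate sample ids are an
  error — no guessing.

# Known limitations

* **Unmatched control sets.**  The bottom-K "control" SNPs are not
  frequency-matched to the top-K set (matching is deliberately not
  applied, following the design this package reimplements).  Mean D̂²
  over a finite sample has a sampling floor that scales with
  pAqA·pBqB/(2n), which varies ~20-fold across the MAF spectrum, so
  |loading| ranking can induce small systematic floor differences
  between sets.  Moreover, because the PCA is fitted on the same
  parents the statistics are computed on, even noise loadings select
  marker sets with genuine in-sample correlation.  Consequently the
  top-vs-bottom t-test is anticonservative under structureless nulls;
  the test suite documents this behaviour rather than hiding it, and
  any population with standing ancestry variance carries true
  admixture LD at ancestry-informative markers irrespective of
  current-generation mate choice.
* The t-test treats the 1000 iteration means as independent although
  they share samples; this follows the reimplemented design and is
  flagged in the output metadata.
* The copula mating model guarantees target spousal correlations but
  is silent about mechanism; it cannot represent, e.g., geographic
  sorting dynamics.
* Fractional-change figures from correlation adjustment are reported
  at full precision; reconciling them with rounded published
  correlation digits is not attempted.

# Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to keep the full suite
in minutes while leaving clear signal margins: cohorts of 60–1,000
families with 150–2,000 markers for module tests; the D² comparison at
500 families × 2,000 SNPs × 100 iterations (K = 100); the pTDT check
ascertains ~500 simplex trios from 13,000 simulated families at 2%
prevalence; the θ checks use 2,000 offspring and 2,000 markers; EM
oracle equivalence uses 100 random tables of up to 50 individuals
against a grid search refined to 5e-6.

# Reproducing an analysis

```{r}
library(amstruct)

cfg <- pipeline_config(
  sim = sim_config(n_snps = 2000, n_families = 500, fst = 0.01,
                   rho_ancestry = 0.5),
  n_iter = 100, top_k = 100, out_dir = "am_run", seed = 1)
res <- run_pipeline(cfg)
print(res$ldstruct)
```

Identical configuration and seed reproduce identical outputs, including
the per-iteration tables and the manifest.
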