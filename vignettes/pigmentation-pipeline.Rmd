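---
title: "Methods: quantitative pigmentation phenotyping, association layers and sweep inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative pigmentation phenotyping, association layers and sweep inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pigmentr implements, as a single tested pipeline, the computational layers of
a pigmentation genetics study in an admixed cohort: quantitative eye-color
phenotyping from iris pixels, covariate-adjusted association analysis with
conditioning, stepwise, epistasis, multivariate and meta-analytic layers,
selection scans with empirical significance, allele-frequency–environment
correlation under a population-structure null, and approximate Bayesian
computation (ABC) of a selective sweep's coefficient and onset. Because raw
cohort genotypes and phenotypes of such studies are access-restricted, every
input can be produced by the package's synthetic-data generators, which are
first-class, tested code. This vignette records the models, the tunable
parameters, and the design choices made where the design was genuinely open.

## Iris color phenotyping

A photographed iris enters the pipeline as a cloud of RGB pixels plus two
reference colors from the same photograph: the whitest sclera pixel and the
darkest pupil pixel. `normalize_pixels()` applies the per-channel affine map
sending pupil to 0 and sclera to 255. The normalization could equally have
been implemented as a gain-only white balance; the affine form is used
because the darkest-pupil reference exists precisely to anchor the black
point, and is flagged as a choice. `remove_highlights()` operationalizes the
"adaptive threshold" for specular reflections as dropping pixels whose
bicone lightness exceeds `mean + k * SD` (default `k = 2`) of the cloud's
lightness distribution; the threshold adapts to each iris's brightness. If
the rule would empty the cloud, the darkest half is kept.

The iris color is the *geometric median* of the remaining pixels
(`multivariate_median()`, Weiszfeld iteration with the Vardi–Zhang
correction, tolerance `1e-6` per channel). The geometric median treats the
iris color as one point in RGB space and resists the heavy tails that
residual highlights produce; channel-wise medians are available
(`channelwise = TRUE`) as a sensitivity check.

RGB is converted to the bicone hue–chroma–lightness space with the standard
hexagonal formulas: `L = (max + min)/2`, `C = max − min`, H the hexagonal
angle with red at 0°, green at 120°, blue at 240°. These are the standard
RGB-derived bicone formulas: saturated colors sit at the equator
(`L = 0.5`) and chroma collapses at both apexes. Iris hues concentrate near
a plane through the vertical axis at roughly 20°, so hue is standardized as
`cos(H − 20°)`: +1 for brown/olive eyes, −1 for blue/gray. The 20° reference
is the default but can be recomputed from a sample via `circular_median()`
(arc-length minimizer over observed angles, ties to the smallest angle).
The sine component varies little for eye colors (the cloud is nearly
planar) and is deliberately not used.

`generate_iris_pixels()` emulates this input: Gaussian RGB noise (default
SD 6 on the 0–255 scale) around a bicone center, near-white specular pixels
at a stated fraction, and reference triples. It does *not* emulate spatial
iris structure (crypts, limbal rings) or correlated sensor noise, so a
passing round-trip (center recovered within 2° in H and 0.02 in C and L at
up to 20% highlight contamination) validates the estimator chain, not
photograph segmentation.

## Association layers

`gwas_scan()` fits, per SNP, ordinary least squares of the trait on the
additive dosage plus covariates — age, sex and the first six genetic PCs by
default — with a two-sided t test on the dosage term. Ordinal traits (hair
in four categories, eye color in five) are analyzed on their category
codes, matching common linear-model GWAS practice. Missing data are handled
complete-case per trait; the source protocol does not state its handling,
and complete-case is the most transparent default. Monomorphic SNPs are
flagged rather than tested; a tested SNP collinear with the conditioning
set is an error naming the pair.

The layered design follows the study structure:

* **Conditioned scan** — established large-effect SNPs enter as covariates,
  exposing signals they otherwise mask.
* **Stepwise signals** — within a region, the smallest-P SNP joins the
  conditioning set while the smallest conditional P value remains below
  `5e-8`; the stop rule mirrors "significance abolished" reasoning, with
  genome-wide (`5e-8`) and suggestive (`1e-5`) thresholds fixed constants.
* **Epistasis scan** — every unordered pair of index SNPs is tested for a
  dosage-product interaction, Bonferroni-corrected over pairs per trait
  (`0.05 / choose(k, 2)`; 18 SNPs give `3.27e-4`). Cross-trait correction
  is deliberately not applied: the per-trait pair family is the unit the
  threshold reproduces.
* **Multivariate Wald** — reverse regression of the dosage on all
  phenotypes jointly (plus covariates), chi-square with df = number of
  phenotypes.
* **Meta-analysis** — fixed-effect inverse-variance pooling of per-stratum
  (e.g. per-country) coefficients; strata are treated as independent
  pre-fit scans.

Two diagnostics summarize a whole scan. The tail strength of the ordered P
values,

$$\mathrm{TS} = \frac{1}{n}\sum_{k=1}^{n}\left(1 - p_{(k)}\frac{n+1}{k}\right),$$

is 0 under the global null and grows with polygenicity; its asymptotic SD
is `1/sqrt(n*)` with `n*` the effective (LD-pruned) number of independent
SNPs, giving a ±3 SD null band. The genomic inflation factor is the median
association chi-square over `qchisq(0.5, 1)`.

## Selection scans

`reynolds_fst()` implements a coancestry estimator in the Reynolds–Weir–
Cockerham drift model: the squared sample-frequency difference is corrected
for binomial sampling so its expectation is the between-population variance
component, and the denominator adds an unbiased within-population term.
Estimates may be slightly negative for undifferentiated pairs; multi-SNP
estimates are ratios of summed components. The population branch statistic
transforms pairwise FST to branch lengths `T = −log(1 − FST)` and allocates
`PBS = (T_f1 + T_f2 − T_12)/2` to the focal population; negative FST is
truncated to zero only inside the log (raw values are reported), and a pair
monomorphic for the same allele contributes zero divergence. SNPs enter the
scan when they are polymorphic across at least two populations considered
jointly — a fixed inter-population difference is retained, since that is
the configuration with maximal FST.

`ehh()` computes extended haplotype homozygosity by exact pair counting
within the core-allele class, and `ihs()` integrates it over genetic
distance (trapezoid rule) separately for ancestral and derived classes,
truncating at EHH < 0.05 or 1 Mb per side. SNPs with derived frequency
outside (5%, 95%) and SNPs whose EHH has not decayed below 0.05 within the
truncation distance are excluded, turning the published exclusion rule into
an explicit filter. Unstandardized scores `ln(iHH_A/iHH_D)` are
standardized within derived-allele-frequency bins (default 2% bins, a
selscan-like width; the bin width is configurable because the source
protocol does not state it). Physical distance is used for the 1 Mb
truncation; a genetic-distance cap would also be defensible, and the
parameter is exposed.

`tajimas_d()` tiles the region with half-open, non-overlapping 10 kb
windows and drops windows with fewer than five segregating sites. Empirical
P values for all scans are outlier ranks: rank from the relevant tail over
the number of scores, ties sharing the worst rank (the tie rule is a
package decision; the source does not state one), with significance called
below 0.01.

Haplotype blocks use the Gabriel confidence-interval classification:
two-SNP haplotype frequencies by EM from unphased dosages, a
likelihood-profile interval on |D′| (grid 0–1, 5th/95th percentiles),
strong LD at bounds (0.70, 0.98), strong recombination below 0.90, the 95%
informative-pair rule, longest-first non-overlapping selection, and a
500 kb pair-distance cap. Blocks with fewer than five SNPs are discarded
downstream. Enrichment of per-block maximum PBS or |iHS| at blocks holding
associated SNPs (association P below `1e-5`) against the rest uses a
one-sided Mann–Whitney U test (normal approximation with tie correction;
an exact mode exists and is cross-checked against full enumeration in the
tests).

## Allele frequency and solar radiation

`estimate_structure()` builds the null: control-SNP frequencies are
variance-stabilized (arcsin square root), centered across populations per
SNP, and their sample covariance (ridge `1e-6`) is the between-population
structure matrix. `env_bayes_factor()` is a conjugate-Gaussian analysis of
the same contrast the MCMC-based method targets: transformed frequencies
are modeled as Gaussian with the structure covariance, the environment
(standardized) enters as a mean shift with a N(0, 1) prior on the slope
integrated by 1-D quadrature, and the Bayes factor compares this to the
slope-zero model. It is documented as a surrogate: agreement with the MCMC
method is claimed at the level of detection behavior, not BF values.
`env_spearman()` gives the rank correlation, with empirical P values from
the rank of |ρ| among a caller-supplied control set (its composition is a
parameter, since the reference set is analysis-specific); a SNP is called
significant only when both lines of evidence are (strict conjunction,
threshold 0.05). Regional analyses are row filters on the region label.

## Sweep simulation and ABC

`simulate_sweep()` is a rescaled forward Wright–Fisher simulator (compiled
code) on a continuous segment with infinite-sites mutation and crossover
recombination. The demography is a configurable three-population
out-of-Africa stand-in — ancestral population, AFR/Eurasia split (default
70 kya), out-of-Africa bottleneck, EUR/EAS split (default 45 kya),
exponential growth to the present, symmetric migration — because the
original study's demographic parameter table is not public. Defaults:
`N_anc = 7000`, `N_afr = 4000`, `N_ooa = 1800`, EUR and EAS growing from
1000 to 8000 diploids, generation time 25 y, mutation `1.25e-8` and
recombination `1e-8` per bp per generation. The migration default
(`3e-4` per unscaled generation) was calibrated once so that *neutral*
pairwise FST between the simulated populations falls in the 0.10–0.16
range observed between human continental populations; without migration
the stand-in sizes produce implausibly drifted backgrounds.

Everything is rescaled by `Q` (default 10): sizes and epoch lengths divided
by `Q`, mutation, recombination and selection multiplied by `Q`, so that a
desk-scale run preserves the products that control diversity, LD and sweep
dynamics; an unscaled `Q = 1` run reproduces the full-size regime.
Ancestral standing variation is initialized from the neutral equilibrium
frequency spectrum with sites drawn independently — a coalescent-exact
burn-in is intentionally avoided — and linkage structure then accumulates
over the simulated epochs; under a constant-size control demography the
simulator's Tajima's D is centered near the neutral expectation, which is
the property the initialization must preserve. At the onset generation the
central derived allele is set to 1% frequency in EUR and EAS (absent in
AFR) and is thereafter selected in EAS only with additive fitnesses
`1, 1 + s/2, 1 + s` (the additive scheme of comparable sweep-dating
studies; genic selection is a configuration switch). Replicates that lose
the allele are *retained* with derived frequency 0 by default — the
frequency is itself a summary statistic — with a resample-on-loss option.

`summarize_sweep()` computes, in a window centered on the selected site
(200 kb at full scale), ten quantities: π, Tajima's D, Fu & Li's D and F
(singletons polarized by ancestral state), Garud's H1, H2, H2/H1, FST of
EAS against EUR and against AFR, and the selected site's derived
frequency. Single-population statistics use the EAS sample, the population
in which selection acts; the enumeration usually counted as "nine
statistics" treats the three H statistics as one haplotype-diversity
family, and any one column can be dropped by configuration. Summary
statistics are Box-Cox transformed (per statistic: shift so the minimum
lies in [1, 2], then the profile-likelihood λ), reduced by partial least
squares fitted on a 10,000-simulation subset, and the first seven
components (unit-variance on the fit subset) carry the Euclidean distance
for rejection: the closest 0.5% of draws form the posterior, summarized by
the median and the 2.5/97.5 percentiles. Distance is taken in PLS space —
the reduction exists precisely to define the metric — and no post-rejection
regression adjustment is applied. Leave-one-out validation reports the MSE
of the posterior median over the prior variance.

Desk-scale test sizes (stated here as the package's choices): reference
tables of 20,000 simulations on 50 kb segments with 20 kb summary windows
and 50 sampled haplotypes per population; detectability experiments on
2 Mb segments with 100 haplotypes, where the EHH-decay filter has room to
operate. The uniform priors are `s ~ U(0, 0.05)` and onset
`~ U(5000, 42229)` years ago; onset times are converted to generations at
25 y/generation (a convention the source does not state).

## What the synthetic data do and do not establish

The cohort generator draws ancestry-specific allele frequencies from
Beta(0.5, 0.5) — producing the strong cross-ancestry differentiation that
pigmentation loci show — Dirichlet admixture proportions (defaults
emulating a 48/46/6 European/Native American/African mix), binomial
genotypes, additive traits with noise scaled to a target heritability, and
liability-threshold ordinal traits. It makes no attempt to emulate LD
within ancestries, imputation error, or genotyping artifacts; association
tests passing on these cohorts validate the estimators and their error
control, not robustness to real-data pathologies. Likewise the
population–environment generator produces exchangeable-structure
frequencies around an environmental gradient, not real geography.

## Numerical choices and limitations

Weiszfeld iterations stop at `1e-6` per channel with the standard
correction at data points; EHH uses exact integer pair counts; empirical P
values are never zero (minimum `1/n`); the D′ CI grid step is 0.005;
Box-Cox λ is profiled on a grid of step 0.05 in [−2, 2]; rejection ties are
broken by simulation index for determinism. Known limitations: the forward
simulator's standing-variation initialization underestimates long-range LD
at the very start of the simulated period; the Bayes-factor surrogate does
not reproduce MCMC BF scales; haplotype-block finding is quadratic in SNPs
per region and intended for regional, not genome-wide, use at desk scale.
One consequence of the sweep model worth flagging: because selection
starts from a 1% standing frequency (many haplotype backgrounds), the
simulated sweeps are soft, and in the packaged detectability experiment
the selected site clears genome-wide empirical significance for PBS in
over 80% of replicates but for |iHS| in only about 65–70% — haplotype-score
power for soft sweeps is genuinely lower, and the experiment reports it
rather than hiding it.
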