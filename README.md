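# pigmentr

Tools for genetic studies of human pigmentation in admixed cohorts, built
as one tested pipeline that runs end-to-end on synthetic data. It covers
the four computational layers such studies chain together:

1. **Quantitative eye-color phenotyping.** Iris pixel clouds are
   normalized against sclera/pupil references, cleared of specular
   highlights by an adaptive lightness threshold, summarized by the
   geometric median in RGB, and expressed in the bicone
   hue–chroma–lightness space, with hue standardized as `cos(H − 20°)`
   (+1 brown, −1 blue/gray).
2. **Layered association testing.** Additive-dosage linear regression
   adjusted for age, sex and genetic PCs; conditioned scans on established
   variants; stepwise detection of independent signals (stop at
   `P ≥ 5×10⁻⁸`); pairwise epistasis with a Bonferroni threshold of
   `0.05 / C(k,2)`; a reverse-regression multivariate Wald test;
   fixed-effect meta-analysis; and the polygenicity diagnostics
   TS = (1/n) Σₖ (1 − p₍ₖ₎ (n+1)/k) (null value 0, SD `1/√n*`) and the
   genomic inflation factor λ.
3. **Selection scans.** Reynolds-model FST and the population branch
   statistic PBS = (T₁ + T₂ − T₁₂)/2 with T = −log(1 − FST); EHH and the
   integrated haplotype score with the standard frequency and EHH-decay
   filters and frequency-bin standardization; windowed Tajima's D (10 kb,
   ≥5 SNPs); genome-wide empirical P values (outlier ranks, significance
   at 0.01); Gabriel confidence-interval haplotype blocks and a one-sided
   Mann–Whitney enrichment test of per-block maximum scores at associated
   regions.
4. **Environmental correlation and sweep dating.** Allele-frequency vs
   solar-radiation tests under a population-structure null (conjugate
   Gaussian Bayes factor + Spearman ρ, joint significance rule), and a
   rejection-ABC estimator of a sweep's selection coefficient and onset
   time over a rescaled forward Wright–Fisher simulator, with Box-Cox
   transformed, PLS-reduced summary statistics (π, Tajima's D, Fu & Li's
   D and F, Garud's H1/H2/H2H1, two FSTs, derived allele frequency) and
   the closest 0.5% of draws accepted.

Every input the pipeline consumes — admixed genotype/phenotype cohorts,
iris pixel clouds, population–environment tables, sweep haplotype panels —
can be produced by the package's synthetic-data generators, so the whole
analysis is testable without access-restricted cohort data.

## Worked example

Simulate a sweep (selection coefficient 2%, onset 15,000 years ago),
summarize it, and estimate the parameters against a small reference table:

```r
library(pigmentr)

sim <- simulate_sweep(sweep_params(0.02, 15000), segment = 5e4, seed = 2)
sim
#> <sweep_sim> s = 0.02, onset = 15000 ya; EAS DAF = 0.62

round(summarize_sweep(sim, window = 2e4), 3)
#>          pi   tajimas_d     fu_li_d     fu_li_f          h1          h2
#>       4.127      -1.039      -0.316      -0.708       0.383       0.023
#>       h2_h1 fst_eas_eur fst_eas_afr         daf
#>       0.061       0.495       0.476       0.620

tab <- abc_reference_table(2000, seed = 1)      # 20,000 at full desk scale
fit <- abc_sweep_fit(summarize_sweep(sim, 2e4), tab, tolerance = 0.005)
summary(fit)
#> Rejection ABC sweep fit
#>   simulations: 2000 (PLS fit) of 2000; components: 7; tolerance: 0.005
#>   posterior (median [95% CI]):
#>     s     : 0.0134 [0.0011, 0.0367]
#>     onset : 22418 ya [11732, 39821]
```

The 95% credible intervals cover both true parameters (the onset is only
weakly identified, as its wide interval shows); at the documented desk
scale (20,000 simulations) the `s` interval covers a true `s = 0.02` in
50 of 50 replicate pseudo-observations (seed 1 of the acceptance script).

The phenotyping and association layers run the same way:

```r
ps  <- generate_iris_pixels(c(30, 0.3, 0.4), n_pixels = 600,
                            highlight_fraction = 0.2, seed = 1)
iris_color(ps)
#>      rgb_r   rgb_g  rgb_b    H_deg         C         L  cosH_std
#> 1 140.7102 100.967 62.249 29.60799 0.3076908 0.3979591 0.9859728

coh <- generate_admixed_cohort(cohort_spec(
  2000, 100, causal_snps = data.frame(snp = 42, beta = 0.6), seed = 7))
scan <- gwas_scan(coh$genotypes, coh$phenotypes, "trait")
scan[which.min(scan$p), c("snp", "beta", "se", "p")]
#>      snp      beta         se p
#> 42 snp42 0.6000613 0.00491152 0
```

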