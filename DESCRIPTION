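Package: pigmentr
Title: Quantitative Pigmentation Phenotyping, Association Testing and
    Selective Sweep Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for genetic studies of human pigmentation
    in admixed cohorts. Converts iris pixel clouds into quantitative
    hue/chroma/lightness phenotypes; runs covariate-adjusted, conditioned,
    stepwise and epistatic association scans with polygenicity diagnostics
    (tail strength, genomic inflation); computes selection statistics
    (Reynolds FST, the population branch statistic, EHH/iHS, Tajima's D,
    Fu and Li's D and F, Garud's H statistics) with genome-wide empirical
    P values and haplotype-block enrichment tests; tests allele-frequency
    correlation with solar radiation under a population-structure null; and
    estimates a sweep's selection coefficient and onset time by rejection
    approximate Bayesian computation over a rescaled forward Wright-Fisher
    simulator, with Box-Cox transformed, PLS-reduced summary statistics.
    Every input can be generated synthetically, so the whole pipeline is
    testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    mixOmics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
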