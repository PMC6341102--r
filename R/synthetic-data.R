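#' Specification of a synthetic admixed cohort
#'
#' Describes the generator that emulates a three-way admixed study sample:
#' per-individual ancestry proportions drawn from a Dirichlet distribution,
#' ancestry-specific allele frequencies with high between-ancestry
#' differentiation, additive quantitative traits with a few large-effect
#' variants, and ordinal (categorical) traits obtained by thresholding a
#' latent liability.
#'
#' @param n_individuals number of individuals (>= 2).
#' @param n_snps number of SNPs.
#' @param n_ancestries number of ancestral populations (default 3).
#' @param admixture_concentration Dirichlet concentration; large values give
#'   near-identical ancestry profiles, small values strong admixture
#'   structure. May be a vector of per-ancestry concentrations (default
#'   `c(4.8, 4.6, 0.6)`, emulating roughly 48/46/6 percent mean ancestry).
#' @param causal_snps data frame with columns `snp` (index) and `beta`
#'   (effect in trait-SD units), or `NULL` for a fully null cohort.
#' @param trait_heritability narrow-sense heritability target in `[0, 1]`.
#' @param freq_shape shape of the symmetric Beta prior on ancestral allele
#'   frequencies (default 0.5: strongly differentiated ancestries).
#' @param seed integer seed.
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_individuals, n_snps, n_ancestries = 3L,
                        admixture_concentration = c(4.8, 4.6, 0.6),
                        causal_snps = NULL, trait_heritability = 0.5,
                        freq_shape = 0.5, seed = 1L) {
  stopifnot(n_individuals >= 2, n_snps >= 1, n_ancestries >= 1)
  if (length(admixture_concentration) == 1L)
    admixture_concentration <- rep(admixture_concentration, n_ancestries)
  stopifnot(length(admixture_concentration) == n_ancestries,
            all(admixture_concentration > 0))
  if (!is.null(causal_snps)) {
    causal_snps <- as.data.frame(causal_snps)
    stopifnot(all(c("snp", "beta") %in% names(causal_snps)),
              all(causal_snps$snp >= 1), all(causal_snps$snp <= n_snps))
    if (nrow(causal_snps) > 0 && any(causal_snps$beta != 0) &&
        trait_heritability == 0)
      stop("heritability 0 is inconsistent with nonzero causal effects")
  }
  if (trait_heritability < 0 || trait_heritability > 1)
    stop("trait_heritability must lie in [0, 1]")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_snps = as.integer(n_snps),
                 n_ancestries = as.integer(n_ancestries),
                 admixture_concentration = admixture_concentration,
                 causal_snps = causal_snps,
                 trait_heritability = trait_heritability,
                 freq_shape = freq_shape, seed = as.integer(seed)),
            class = "cohort_spec")
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), ncol = length(alpha),
              byrow = TRUE)
  x / rowSums(x)
}

#' Generate a synthetic admixed cohort
#'
#' Draws ancestry proportions `q_i ~ Dirichlet(alpha)`, ancestry-specific
#' allele frequencies `f_ka ~ Beta(shape, shape)` independently per SNP and
#' ancestry, genotypes `g_ik ~ Binomial(2, q_i . f_k)`, and builds:
#' a continuous trait
#' `y = sum(beta_j g_j) + covariate effects + e`, with the noise variance set
#' so the realized genetic variance over total variance matches the target
#' heritability; and ordinal hair (4 categories) and eye (5 categories)
#' traits by thresholding a latent liability at fixed category frequencies.
#' Age and sex covariates have real (small) effects so that covariate
#' adjustment matters; genetic PCs are computed from the genotype matrix.
#'
#' @param spec a [cohort_spec].
#' @return A list with elements `genotypes` (n x m dosage matrix, colnames
#'   `snp1..`), `phenotypes` (data frame: `trait`, `hair`, `eye`, `age`,
#'   `sex`, `PC1..PC6`), `admixture` (n x K matrix), `ancestral_freqs`
#'   (m x K), and `spec`.
#' @export
generate_admixed_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_individuals; m <- spec$n_snps; K <- spec$n_ancestries
  q <- .rdirichlet(n, spec$admixture_concentration)
  f <- matrix(stats::rbeta(m * K, spec$freq_shape, spec$freq_shape), m, K)
  p_ind <- q %*% t(f)                       # n x m expected frequency
  g <- matrix(stats::rbinom(n * m, 2L, as.vector(p_ind)), n, m)
  colnames(g) <- paste0("snp", seq_len(m))

  age <- round(stats::runif(n, 18, 85))
  sex <- stats::rbinom(n, 1L, 0.5)
  npc <- min(6L, n - 1L, m)
  pcs <- stats::prcomp(g, center = TRUE, scale. = FALSE)$x[, seq_len(npc), drop = FALSE]
  colnames(pcs) <- paste0("PC", seq_len(npc))

  gen_comp <- numeric(n)
  if (!is.null(spec$causal_snps) && nrow(spec$causal_snps) > 0)
    gen_comp <- as.vector(g[, spec$causal_snps$snp, drop = FALSE] %*%
                            spec$causal_snps$beta)
  vg <- stats::var(gen_comp)
  h2 <- spec$trait_heritability
  cov_eff <- 0.02 * (age - mean(age)) + 0.3 * sex
  # the non-genetic budget vg*(1-h2)/h2 is split between covariate effects
  # and noise so realized vg / var(y) matches the target heritability
  if (vg > 0 && h2 > 0) {
    budget <- vg * (1 - h2) / h2
    if (stats::var(cov_eff) > 0.9 * budget)
      cov_eff <- cov_eff * sqrt(0.9 * budget / stats::var(cov_eff))
    ve <- budget - stats::var(cov_eff)
  } else ve <- 1
  trait <- gen_comp + cov_eff + stats::rnorm(n, 0, sqrt(ve))

  # ordinal traits from a latent liability sharing the genetic component
  liab <- gen_comp + stats::rnorm(n, 0, sqrt(max(ve, 1e-12)))
  cut_at <- function(x, probs) {
    br <- stats::quantile(x, cumsum(probs)[-length(probs)])
    findInterval(x, br) + 1L
  }
  hair <- cut_at(liab, c(0.15, 0.35, 0.35, 0.15))   # 1..4
  eye  <- cut_at(liab, c(0.10, 0.20, 0.40, 0.20, 0.10)) # 1..5

  pheno <- data.frame(trait = trait, hair = hair, eye = eye,
                      age = age, sex = sex, pcs, check.names = FALSE)
  list(genotypes = g, phenotypes = pheno, admixture = q,
       ancestral_freqs = f, spec = spec,
       genetic_component = gen_comp)
}

#' Generate a synthetic iris pixel cloud
#'
#' Emulates the pixel sets extracted from iris photographs: Gaussian RGB
#' noise around a center color given in bicone HCL coordinates, a white
#' sclera reference, a darkest-pupil reference, and a stated fraction of
#' near-white specular-highlight pixels.
#'
#' @param center_hcl length-3 vector `(H degrees, C, L)`; must lie inside
#'   the bicone (`C <= 1 - |2L - 1|`).
#' @param n_pixels number of iris pixels (>= 1).
#' @param highlight_fraction fraction of additional near-white highlight
#'   pixels injected into the cloud, in `[0, 1]`.
#' @param noise_sd per-channel Gaussian noise SD on the 0--255 scale
#'   (default 6; 0 gives an exact point cloud).
#' @param seed integer seed.
#' @return A [pixel_set]; highlight pixels, if any, are appended after the
#'   iris pixels.
#' @export
generate_iris_pixels <- function(center_hcl, n_pixels, highlight_fraction = 0,
                                 noise_sd = 6, seed = 1L) {
  stopifnot(n_pixels >= 1, highlight_fraction >= 0, highlight_fraction <= 1)
  set.seed(seed)
  center <- hcl_to_rgb(center_hcl[1], center_hcl[2], center_hcl[3])
  px <- matrix(rep(center, each = n_pixels), n_pixels, 3)
  if (noise_sd > 0)
    px <- px + matrix(stats::rnorm(n_pixels * 3, 0, noise_sd), n_pixels, 3)
  n_hl <- round(highlight_fraction * n_pixels)
  if (n_hl > 0) {
    hl <- matrix(stats::runif(n_hl * 3, 235, 255), n_hl, 3)
    px <- rbind(px, hl)
  }
  px <- pmin(pmax(px, 0), 255)
  pixel_set(px, white_ref = c(252, 252, 252), pupil_ref = c(3, 3, 3))
}

#' Generate a population-by-environment table
#'
#' Emulates a panel of native population samples with an environmental
#' gradient (mean annual solar radiation): transformed allele frequencies
#' (arcsin-square-root scale) are drawn from a multivariate normal with mean
#' `alpha + beta_env * env` and a supplied between-population covariance
#' (the population-structure null), then back-transformed to `[0, 1]`.
#'
#' @param n_pops number of populations (>= 3; fewer makes rank correlation
#'   meaningless and is rejected).
#' @param covariance `n_pops x n_pops` symmetric positive-definite matrix of
#'   the transformed frequencies (default identity scaled by 0.02).
#' @param beta_env effect of the standardized environment on the transformed
#'   frequency (default 0).
#' @param alpha baseline transformed frequency (default `asin(sqrt(0.3))`).
#' @param env_range range of solar radiation values, kWh/m2/day.
#' @param n_ind_range range of per-population sample sizes (individuals,
#'   minimum 10).
#' @param seed integer seed.
#' @return A data frame with columns `population`, `lat`, `lon`, `n_alleles`,
#'   `solar_kwh_m2_day`, `derived_freq`, `region`.
#' @export
generate_pop_env_table <- function(n_pops, covariance = NULL, beta_env = 0,
                                   alpha = asin(sqrt(0.3)),
                                   env_range = c(2.5, 6.5),
                                   n_ind_range = c(10, 60), seed = 1L) {
  if (n_pops < 3) stop("need at least 3 populations")
  if (is.null(covariance)) covariance <- diag(0.02, n_pops)
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance))))
    stop("covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("covariance must be positive definite")
  set.seed(seed)
  env <- seq(env_range[1], env_range[2], length.out = n_pops) +
    stats::rnorm(n_pops, 0, diff(env_range) / (10 * n_pops))
  env_std <- as.vector(scale(env))
  z <- alpha + beta_env * env_std +
    as.vector(t(chol(covariance)) %*% stats::rnorm(n_pops))
  z <- pmin(pmax(z, 0), pi / 2)
  freq <- sin(z)^2
  n_ind <- round(stats::runif(n_pops, n_ind_range[1], n_ind_range[2]))
  data.frame(population = paste0("POP", seq_len(n_pops)),
             lat = stats::runif(n_pops, -40, 65),
             lon = stats::runif(n_pops, -170, 170),
             n_alleles = 2L * n_ind,
             solar_kwh_m2_day = env,
             derived_freq = freq,
             region = rep_len(c("Africa", "Western Eurasia", "Eastern Eurasia"),
                              n_pops))
}
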