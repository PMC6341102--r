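#' Three-population demographic model for sweep simulation
#'
#' A configurable out-of-Africa stand-in demography: one ancestral
#' population splits into an African lineage and a bottlenecked Eurasian
#' lineage, which later splits into European and East Asian lineages that
#' grow exponentially to the present. All sizes and epoch durations are
#' divided by the rescaling factor `Q` (and the mutation, recombination and
#' selection intensities multiplied by `Q`), so that desk-scale forward
#' simulation is feasible; an unscaled run (`Q = 1`) reproduces the
#' full-size regime.
#'
#' @param N_anc,N_afr,N_ooa diploid sizes (unscaled) of the ancestral,
#'   African and out-of-Africa bottleneck populations.
#' @param N_eur,N_eas length-2 vectors `c(size at split, size now)` for the
#'   exponentially growing European / East Asian populations.
#' @param t_split1_ya,t_split2_ya split times in years ago (AFR/Eurasia
#'   must be older than EUR/EAS).
#' @param generation_time years per generation (default 25).
#' @param Q rescaling factor (default 10).
#' @param mu,rec per-bp per-generation mutation and recombination rates
#'   (unscaled).
#' @param migration symmetric per-generation migration probability between
#'   active populations, on the rescaled time scale (default 3e-3, i.e.
#'   3e-4 per unscaled generation, chosen so neutral pairwise FST between
#'   the simulated populations falls in the 0.10-0.16 range typical of
#'   human intercontinental comparisons).
#' @return An object of class `demography_spec`.
#' @export
demography_spec <- function(N_anc = 7000, N_afr = 4000, N_ooa = 1800,
                            N_eur = c(1000, 8000), N_eas = c(1000, 8000),
                            t_split1_ya = 70000, t_split2_ya = 45000,
                            generation_time = 25, Q = 10,
                            mu = 1.25e-8, rec = 1e-8, migration = 3e-3) {
  if (t_split1_ya <= t_split2_ya)
    stop("the AFR/Eurasia split must predate the EUR/EAS split")
  d <- list(N_anc = N_anc, N_afr = N_afr, N_ooa = N_ooa,
            N_eur = N_eur, N_eas = N_eas,
            t_split1_ya = t_split1_ya, t_split2_ya = t_split2_ya,
            generation_time = generation_time, Q = Q,
            mu = mu, rec = rec, migration = migration)
  scl <- function(N) pmax(2L, as.integer(round(N / Q)))
  d$scaled <- list(N_anc = scl(N_anc), N_afr = scl(N_afr),
                   N_ooa = scl(N_ooa), N_eur = scl(N_eur),
                   N_eas = scl(N_eas),
                   t_split1 = max(2L, as.integer(round(
                     t_split1_ya / (generation_time * Q)))),
                   t_split2 = max(1L, as.integer(round(
                     t_split2_ya / (generation_time * Q)))),
                   mu = mu * Q, rec = rec * Q)
  if (any(unlist(d$scaled[c("N_anc", "N_afr", "N_ooa", "N_eur", "N_eas")]) < 2))
    stop("rescaled population sizes must be >= 2")
  structure(d, class = "demography_spec")
}

#' Sweep parameters
#'
#' The two inferred quantities: the selection coefficient per derived
#' allele copy (additive fitnesses 1, 1+s/2, 1+s) and the onset time of
#' selection in years before present. Prior support follows the uniform
#' priors used for inference: s in `[0, 0.05]`, onset in `[5000, 42229]`
#' years ago.
#'
#' @param s selection coefficient (unscaled).
#' @param t_sel_ya onset of selection, years ago.
#' @param check enforce the prior support (default `TRUE`).
#' @return An object of class `sweep_params`.
#' @export
sweep_params <- function(s, t_sel_ya, check = TRUE) {
  if (check) {
    if (s < 0 || s > 0.05) stop("s outside the prior support [0, 0.05]")
    if (t_sel_ya < 5000 || t_sel_ya > 42229)
      stop("t_sel_ya outside the prior support [5000, 42229]")
  }
  structure(list(s = s, t_sel_ya = t_sel_ya), class = "sweep_params")
}

# neutral equilibrium standing variation for the ancestral population:
# site count from Watterson's expectation, frequencies from the 1/i SFS,
# carriers assigned independently per site (linkage builds up during the
# simulated epochs)
.init_standing_variation <- function(n_hap, theta_region, L) {
  a_n <- sum(1 / seq_len(n_hap - 1))
  S0 <- stats::rpois(1, theta_region * a_n)
  if (S0 == 0) S0 <- 1
  counts <- sample(seq_len(n_hap - 1), S0, replace = TRUE,
                   prob = 1 / seq_len(n_hap - 1))
  H <- matrix(0L, n_hap, S0)
  for (j in seq_len(S0)) H[sample.int(n_hap, counts[j]), j] <- 1L
  pos <- sort(stats::runif(S0, 1, L))
  list(H = H, pos = pos)
}

#' Simulate a selective sweep under the rescaled demography
#'
#' Runs the forward Wright-Fisher simulation: ancestral standing variation
#' is drawn from the neutral equilibrium frequency spectrum, the three
#' populations then evolve with recombination, infinite-sites mutation and
#' drift; at the generation corresponding to the onset time the central
#' derived allele is set to frequency `init_freq` in the European and East
#' Asian pools (absent in Africa) and thereafter is selected in East
#' Asians only. Samples are drawn at present.
#'
#' @param params a [sweep_params].
#' @param demography a [demography_spec].
#' @param segment segment length in bp (default 5e5; the selected site sits
#'   at the center).
#' @param n_sample haplotypes sampled per population (default 50).
#' @param init_freq frequency at the onset of selection (default 0.01).
#' @param on_loss `"retain"` (default: keep the replicate, derived allele
#'   frequency 0) or `"resample"` (retry with fresh randomness up to
#'   `max_retries`, then retain).
#' @param max_retries retry cap for `on_loss = "resample"`.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return A list of class `sweep_sim`: `panels` (named list of
#'   [haplotype_panel]s for AFR, EUR, EAS), `selected_col` (SNP column of
#'   the selected site, `NA` if the allele never segregated into the
#'   sample), `selected_pos`, `daf_eas`, `lost`, `attempts`, `params`,
#'   `demography`.
#' @export
simulate_sweep <- function(params, demography = demography_spec(),
                           segment = 5e5, n_sample = 50, init_freq = 0.01,
                           on_loss = c("retain", "resample"),
                           max_retries = 10L, seed = NULL) {
  on_loss <- match.arg(on_loss)
  stopifnot(inherits(params, "sweep_params"),
            inherits(demography, "demography_spec"))
  if (!is.null(seed)) set.seed(seed)
  sc <- demography$scaled
  gen_years <- demography$generation_time * demography$Q
  t_sel <- as.integer(round(params$t_sel_ya / gen_years))
  if (t_sel >= sc$t_split2)
    stop("selection onset must postdate the EUR/EAS split")
  t_sel <- max(t_sel, 1L)
  s_scaled <- params$s * demography$Q

  t1 <- sc$t_split1; t2 <- sc$t_split2
  grow <- function(N) {  # N = c(size at split, size now), exponential path
    g <- 0:(t1 - 1)
    frac <- pmax(0, (t2 - g) / t2)        # 1 at present, 0 at the split
    out <- as.integer(round(N[1] * (N[2] / N[1])^frac))
    out[g >= t2] <- 0L
    pmax(out, ifelse(g < t2, 2L, 0L))
  }
  # schedules indexed by gens-before-present g (0-based in C++)
  n_afr <- rep(sc$N_afr, t1)
  n_ooa <- ifelse(0:(t1 - 1) >= t2, sc$N_ooa, 0L)
  n_eur <- grow(sc$N_eur)
  n_eas <- grow(sc$N_eas)

  theta <- 4 * sc$N_anc * sc$mu * segment
  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    init <- .init_standing_variation(2L * sc$N_anc, theta, segment)
    res <- wf_sweep_cpp(init$H, init$pos, segment, sc$mu, sc$rec,
                        t2, t_sel, s_scaled, init_freq,
                        as.integer(n_afr), as.integer(n_ooa),
                        as.integer(n_eur), as.integer(n_eas),
                        demography$migration, as.integer(n_sample))
    if (!res$lost || on_loss == "retain" || attempts > max_retries) break
  }

  rate_cM_Mb <- sc$rec * 1e8  # rescaled uniform map
  mk_panel <- function(M) haplotype_panel(M, res$positions,
                                          rate_cM_Mb = rate_cM_Mb)
  structure(list(
    panels = list(AFR = mk_panel(res$afr), EUR = mk_panel(res$eur),
                  EAS = mk_panel(res$eas)),
    selected_col = if (res$selected_col > 0) res$selected_col else NA_integer_,
    selected_pos = segment / 2,
    daf_eas = res$daf_eas, lost = res$lost, attempts = attempts,
    params = params, demography = demography), class = "sweep_sim")
}

#' @export
print.sweep_sim <- function(x, ...) {
  cat("<sweep_sim> s = ", x$params$s, ", onset = ", x$params$t_sel_ya,
      " ya; EAS DAF = ", round(x$daf_eas, 3),
      if (x$lost) " (allele lost)" else "", "\n", sep = "")
  invisible(x)
}
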