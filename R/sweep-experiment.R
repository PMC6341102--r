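#' Sweep detectability experiment
#'
#' Measures how often the selection scans flag a known selected site at
#' genome-wide empirical significance. Neutral replicates of the same
#' demography provide the "genome-wide" background: their PBS scores, and
#' their frequency-bin-standardized |iHS| scores, form the null
#' distributions against which the selected site's empirical P value is
#' computed in each sweep replicate. A replicate counts as detected when
#' the empirical P is below `alpha`; replicates where the selected site
#' fails the scan filters (monomorphic, frequency outside the iHS band,
#' undecayed EHH) count as non-detections.
#'
#' @param n_sweep number of sweep replicates.
#' @param n_background number of neutral replicates used for the null
#'   score distributions.
#' @param s selection coefficient for the sweep replicates.
#' @param t_sel_ya onset of selection (default 10800 ya, a mid-Holocene
#'   onset comparable to inferred pigmentation sweeps).
#' @param demography a [demography_spec].
#' @param segment segment length (default 2e6: long enough flanks for the
#'   EHH decay rule).
#' @param n_sample haplotypes per population (default 100).
#' @param thin compute background iHS at every `thin`-th SNP (default 20).
#' @param bin_width DAF bin width for iHS standardization across the
#'   pooled background (default 0.05).
#' @param alpha empirical significance level (default 0.01).
#' @param seed integer seed.
#' @return A list with `pbs_rate`, `ihs_rate` (detection rates over sweep
#'   replicates), per-replicate detail data frame `detail`, and the
#'   background score pools.
#' @export
sweep_scan_experiment <- function(n_sweep = 25, n_background = 8, s = 0.03,
                                  t_sel_ya = 10800,
                                  demography = demography_spec(),
                                  segment = 2e6, n_sample = 100, thin = 20,
                                  bin_width = 0.05, alpha = 0.01,
                                  seed = 1L) {
  set.seed(seed)
  pbs_of <- function(sim) {
    pc <- panel_counts(sim$panels)
    list(scores = suppressWarnings(
      pbs(pc$counts$EAS, pc$counts$EUR, pc$counts$AFR)$pbs),
      keep = pc$keep)
  }
  # background pools from neutral replicates
  bg_pbs <- c(); bg_ihs_raw <- list()
  for (b in seq_len(n_background)) {
    sim <- simulate_sweep(sweep_params(0, 20000), demography,
                          segment = segment, n_sample = n_sample)
    bg_pbs <- c(bg_pbs, pbs_of(sim)$scores)
    sub <- seq(1, ncol(sim$panels$EAS$H), by = thin)
    sc <- ihs(sim$panels$EAS, snps = sub, standardize = FALSE)
    if (!is.null(sc)) bg_ihs_raw[[b]] <- sc[c("daf", "ihs_unstd")]
  }
  bg_ihs_raw <- do.call(rbind, bg_ihs_raw)
  bg_pbs <- bg_pbs[is.finite(bg_pbs)]
  # genome-wide bin parameters for iHS standardization
  bin_of <- function(daf) pmin(floor(daf / bin_width),
                               round(1 / bin_width) - 1)
  bg_bin <- bin_of(bg_ihs_raw$daf)
  bin_mu <- tapply(bg_ihs_raw$ihs_unstd, bg_bin, mean)
  bin_sd <- tapply(bg_ihs_raw$ihs_unstd, bg_bin, stats::sd)
  std <- function(x, daf) {
    b <- as.character(bin_of(daf))
    mu <- bin_mu[b]; sdv <- bin_sd[b]
    ifelse(is.na(mu) | is.na(sdv) | sdv == 0, NA_real_, (x - mu) / sdv)
  }
  bg_ihs <- abs(std(bg_ihs_raw$ihs_unstd, bg_ihs_raw$daf))
  bg_ihs <- bg_ihs[!is.na(bg_ihs)]

  run_rep <- function(s_rep) {
    sim <- simulate_sweep(sweep_params(s_rep, t_sel_ya), demography,
                          segment = segment, n_sample = n_sample)
    selc <- sim$selected_col
    out <- c(daf = sim$daf_eas, pbs_p = NA_real_, ihs_p = NA_real_)
    if (is.na(selc)) return(out)
    pb <- pbs_of(sim)
    if (selc %in% pb$keep) {
      sc <- pb$scores[which(pb$keep == selc)]
      if (is.finite(sc))
        out["pbs_p"] <- empirical_p(c(sc, bg_pbs), "upper")[1]
    }
    ih <- ihs(sim$panels$EAS, snps = selc, standardize = FALSE)
    if (!is.null(ih)) {
      z <- abs(std(ih$ihs_unstd, ih$daf))
      if (!is.na(z))
        out["ihs_p"] <- empirical_p(c(z, bg_ihs), "upper")[1]
    }
    out
  }
  detail <- as.data.frame(t(vapply(seq_len(n_sweep),
                                   function(i) run_rep(s), numeric(3))))
  list(pbs_rate = mean(!is.na(detail$pbs_p) & detail$pbs_p < alpha),
       ihs_rate = mean(!is.na(detail$ihs_p) & detail$ihs_p < alpha),
       detail = detail, bg_pbs = bg_pbs, bg_ihs = bg_ihs)
}
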