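#' Estimate the population-structure null covariance
#'
#' Builds the null model for allele-frequency--environment testing: per
#' control SNP, population allele frequencies are variance-stabilized
#' (arcsin square root) and centered across populations; the sample
#' covariance of the resulting population vectors across SNPs, with a small
#' ridge on the diagonal, is the between-population structure matrix.
#'
#' @param freqs matrix of control-SNP frequencies (SNPs x populations), in
#'   `[0, 1]`; rows with any missing population are dropped with a notice.
#' @param ridge diagonal shrinkage (default 1e-6).
#' @return A list of class `structure_model` with `omega` (covariance),
#'   `populations`, `n_control`.
#' @export
estimate_structure <- function(freqs, ridge = 1e-6) {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) < 3) stop("need at least 3 populations")
  if (nrow(freqs) < 100) stop("need at least 100 control SNPs")
  cc <- stats::complete.cases(freqs)
  if (!all(cc)) message("dropping ", sum(!cc), " control SNPs with missing populations")
  freqs <- freqs[cc, , drop = FALSE]
  z <- asin(sqrt(pmin(pmax(freqs, 0), 1)))
  z <- z - rowMeans(z)
  omega <- crossprod(z) / (nrow(z) - 1)
  omega <- omega + diag(ridge, ncol(omega))
  structure(list(omega = omega,
                 populations = colnames(freqs) %||% paste0("POP", seq_len(ncol(freqs))),
                 n_control = nrow(z)),
            class = "structure_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log marginal likelihood of z under mean alpha*1 + beta*e, covariance
# omega, with a flat prior on alpha integrated out analytically
.loglik_beta <- function(beta, z, e, omega_inv) {
  r <- z - beta * e
  one <- rep(1, length(z))
  denom <- sum(one * (omega_inv %*% one))
  alpha_hat <- sum(one * (omega_inv %*% r)) / denom
  r <- r - alpha_hat
  -0.5 * sum(r * (omega_inv %*% r)) - 0.5 * log(denom)
}

#' Bayes factor for an environmental effect on allele frequency
#'
#' Support for a linear effect of the (standardized) environment on the
#' variance-stabilized allele frequency, over a null of population
#' structure alone: both models share the structure covariance; the
#' alternative adds a slope with a Gaussian prior, integrated out by 1-D
#' numerical quadrature. This is a conjugate-Gaussian analysis of the same
#' contrast the MCMC-based environmental-correlation method targets; the
#' detection behavior, not the exact BF scale, is the calibrated quantity.
#'
#' @param pop_table data frame with columns `derived_freq` and
#'   `solar_kwh_m2_day` (one row per population, matching the structure
#'   model's population order).
#' @param structure a `structure_model` from [estimate_structure].
#' @param prior_sd Gaussian prior SD on the slope (default 1).
#' @return log10 Bayes factor (alternative over null).
#' @export
env_bayes_factor <- function(pop_table, structure, prior_sd = 1) {
  stopifnot(inherits(structure, "structure_model"))
  e <- pop_table$solar_kwh_m2_day
  if (length(e) != nrow(structure$omega))
    stop("population set does not match the structure model")
  if (stats::sd(e) == 0) stop("environment is constant across populations")
  e <- as.vector(scale(e))
  z <- asin(sqrt(pmin(pmax(pop_table$derived_freq, 0), 1)))
  omega_inv <- solve(structure$omega)
  grid <- seq(-6 * prior_sd, 6 * prior_sd, length.out = 801)
  ll <- vapply(grid, .loglik_beta, numeric(1), z = z, e = e,
               omega_inv = omega_inv)
  lw <- ll + stats::dnorm(grid, 0, prior_sd, log = TRUE)
  mx <- max(lw)
  log_marg <- mx + log(sum(exp(lw - mx)) * (grid[2] - grid[1]))
  log_null <- .loglik_beta(0, z, e, omega_inv)
  (log_marg - log_null) / log(10)
}

#' Spearman correlation of allele frequency with solar radiation
#'
#' Rank correlation between per-population derived allele frequency and
#' mean annual solar radiation, with an empirical P value from the rank of
#' `|rho|` among a reference set of control-SNP `|rho|` values (upper
#' tail). With no reference set, only `rho` is returned.
#'
#' @param pop_table data frame with `derived_freq` and `solar_kwh_m2_day`
#'   (>= 3 populations).
#' @param control_rho optional vector of |rho| values for control SNPs on
#'   the same populations.
#' @return A list with `rho` and `emp_p` (`NA` without controls).
#' @export
env_spearman <- function(pop_table, control_rho = NULL) {
  if (nrow(pop_table) < 3) stop("need at least 3 populations")
  rho <- stats::cor(pop_table$derived_freq, pop_table$solar_kwh_m2_day,
                    method = "spearman")
  emp_p <- NA_real_
  if (!is.null(control_rho) && length(control_rho))
    emp_p <- empirical_p(c(abs(rho), abs(control_rho)), "upper")[1]
  list(rho = rho, emp_p = emp_p)
}

#' Joint significance rule for environmental association
#'
#' A SNP is called associated with solar radiation only if both lines of
#' evidence — the Bayes factor and the rank correlation — are empirically
#' significant (strict inequality at the threshold).
#'
#' @param emp_p_bf empirical P of the Bayes factor.
#' @param emp_p_rho empirical P of `|rho|`.
#' @param threshold significance threshold (default 0.05).
#' @return `TRUE` iff both empirical P values are strictly below the
#'   threshold.
#' @export
joint_significance <- function(emp_p_bf, emp_p_rho, threshold = 0.05) {
  isTRUE(emp_p_bf < threshold) && isTRUE(emp_p_rho < threshold)
}
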