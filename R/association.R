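#' Genome-wide significance thresholds
#'
#' Conventional genome-wide (`5e-8`) and suggestive (`1e-5`) association
#' thresholds, used by the stepwise search and the block-enrichment
#' definition of "associated" regions.
#' @export
GENOME_WIDE_P <- 5e-8

#' @rdname GENOME_WIDE_P
#' @export
SUGGESTIVE_P <- 1e-5

# Build the covariate design (intercept + covariates + conditioning dosages),
# with a collinearity check that names an offending pair.
.assoc_design <- function(G, pheno, covariates, condition_on) {
  X <- matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)"))
  if (length(covariates)) {
    miss <- setdiff(covariates, names(pheno))
    if (length(miss)) stop("covariates not in phenotype table: ",
                           paste(miss, collapse = ", "))
    X <- cbind(X, as.matrix(pheno[covariates]))
  }
  if (length(condition_on)) {
    miss <- setdiff(condition_on, colnames(G))
    if (length(miss)) stop("conditioning SNPs not in genotype matrix: ",
                           paste(miss, collapse = ", "))
    X <- cbind(X, G[, condition_on, drop = FALSE])
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    cc <- suppressWarnings(stats::cor(X[, -1, drop = FALSE]))
    cc[!upper.tri(cc)] <- 0
    bad <- which(abs(abs(cc) - 1) < 1e-10, arr.ind = TRUE)
    if (nrow(bad))
      stop("collinear covariates: ", colnames(cc)[bad[1, 1]], " and ",
           colnames(cc)[bad[1, 2]])
    stop("covariate design is rank deficient")
  }
  X
}

# OLS of y on cbind(X, g); returns beta/se/p for the g term (pivot-safe).
.ols_term <- function(y, X, g) {
  Xg <- cbind(X, g = g)
  fit <- stats::lm.fit(Xg, y)
  if (is.na(fit$coefficients["g"]))
    stop("tested SNP is collinear with the covariates or conditioning set")
  df <- length(y) - fit$rank
  rss <- sum(fit$residuals^2)
  piv <- fit$qr$pivot[seq_len(fit$rank)]
  R <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
  kg <- which(piv == ncol(Xg))
  se <- sqrt(rss / df * R[kg, kg])
  beta <- unname(fit$coefficients["g"])
  tval <- beta / se
  c(beta = beta, se = se,
    p = unname(2 * stats::pt(abs(tval), df, lower.tail = FALSE)),
    n = length(y))
}

#' Single-SNP association scan
#'
#' Per-SNP ordinary least squares of a trait on the additive dosage plus
#' covariates (age, sex and the leading genetic PCs by default) and any
#' conditioning dosages, with a two-sided t test on the dosage term.
#' Ordinal traits are analyzed on their category codes. Rows with missing
#' values in the trait, covariates or dosages are dropped per SNP
#' (complete-case analysis).
#'
#' @param G numeric dosage matrix (individuals x SNPs, entries 0/1/2; column
#'   names are SNP ids).
#' @param pheno data frame of traits and covariates.
#' @param trait name of the trait column.
#' @param covariates character vector of covariate columns (default age,
#'   sex, PC1..PC6 where present).
#' @param condition_on character vector of conditioning SNP ids (appended to
#'   the covariates); must not include the tested SNP.
#' @param snps SNP ids to test (default all non-conditioning columns).
#' @return A data frame with one row per SNP: `snp`, `beta`, `se`, `p`, `n`,
#'   `monomorphic`. Monomorphic SNPs are flagged and carry `NA`
#'   beta/se/p.
#' @examples
#' coh <- generate_admixed_cohort(cohort_spec(300, 50, seed = 2,
#'   causal_snps = data.frame(snp = 7, beta = 1)))
#' head(gwas_scan(coh$genotypes, coh$phenotypes, "trait"))
#' @export
gwas_scan <- function(G, pheno, trait, covariates = NULL,
                      condition_on = character(), snps = NULL) {
  G <- as.matrix(G)
  if (is.null(colnames(G))) colnames(G) <- paste0("snp", seq_len(ncol(G)))
  if (is.null(covariates))
    covariates <- intersect(c("age", "sex", paste0("PC", 1:6)), names(pheno))
  if (is.null(snps)) snps <- setdiff(colnames(G), condition_on)
  if (any(snps %in% condition_on))
    stop("conditioning set overlaps the tested SNPs")
  y_all <- pheno[[trait]]
  if (is.null(y_all)) stop("trait '", trait, "' not found")
  keep0 <- stats::complete.cases(pheno[c(trait, covariates)])
  if (length(condition_on))
    keep0 <- keep0 & stats::complete.cases(G[, condition_on, drop = FALSE])
  X0 <- .assoc_design(G[keep0, , drop = FALSE], pheno[keep0, , drop = FALSE],
                      covariates, condition_on)
  if (sum(keep0) < ncol(X0) + 2) stop("too few complete cases for the design")
  y0 <- as.numeric(y_all[keep0])
  out <- lapply(snps, function(s) {
    g <- G[keep0, s]
    ok <- !is.na(g)
    if (stats::var(g[ok]) == 0)
      return(data.frame(snp = s, beta = NA_real_, se = NA_real_, p = NA_real_,
                        n = sum(ok), monomorphic = TRUE))
    if (length(condition_on) && s %in% colnames(X0)) {
      stop("SNP ", s, " duplicates a conditioning covariate")
    }
    r <- if (all(ok)) .ols_term(y0, X0, g)
         else .ols_term(y0[ok], X0[ok, , drop = FALSE], g[ok])
    data.frame(snp = s, beta = r[["beta"]], se = r[["se"]], p = r[["p"]],
               n = as.integer(r[["n"]]), monomorphic = FALSE)
  })
  do.call(rbind, out)
}

#' Conditioned association scan
#'
#' [gwas_scan] with a set of established large-effect SNPs included as
#' additional covariates, exposing association signals that the conditioned
#' variants would otherwise mask (or absorbing signals they explain).
#'
#' @inheritParams gwas_scan
#' @export
conditioned_scan <- function(G, pheno, trait, condition_on,
                             covariates = NULL, snps = NULL) {
  gwas_scan(G, pheno, trait, covariates = covariates,
            condition_on = condition_on, snps = snps)
}

#' Stepwise search for independent signals in a region
#'
#' Starting from the regional scan, repeatedly adds the smallest-P SNP to
#' the conditioning set and re-scans, while the smallest conditional P value
#' stays below the genome-wide threshold. The accumulated index SNPs are the
#' region's independent signals.
#'
#' @inheritParams gwas_scan
#' @param region_snps SNP ids forming the region.
#' @param threshold stop threshold on the conditional P (default
#'   [GENOME_WIDE_P]).
#' @param max_steps safety cap on the number of signals.
#' @return Character vector of index SNP ids, in discovery order (possibly
#'   empty).
#' @export
stepwise_signals <- function(G, pheno, trait, region_snps, covariates = NULL,
                             threshold = GENOME_WIDE_P, max_steps = 20L) {
  if (!length(region_snps)) stop("empty region")
  index <- character()
  repeat {
    remaining <- setdiff(region_snps, index)
    if (!length(remaining) || length(index) >= max_steps) break
    sc <- gwas_scan(G, pheno, trait, covariates = covariates,
                    condition_on = index, snps = remaining)
    sc <- sc[!sc$monomorphic & !is.na(sc$p), , drop = FALSE]
    if (!nrow(sc) || min(sc$p) >= threshold) break
    index <- c(index, sc$snp[which.min(sc$p)])
  }
  index
}

#' Pairwise epistasis scan among index SNPs
#'
#' For every unordered pair of SNPs fits
#' `trait ~ g1 + g2 + g1:g2 + covariates` and reports the interaction term.
#' The Bonferroni threshold is `0.05 / choose(k, 2)` over the SNP pairs
#' (per trait); with 18 index SNPs this is 0.05/153 = 3.27e-4.
#'
#' @inheritParams gwas_scan
#' @param snps SNP ids to pair up (>= 2).
#' @param alpha family-wise error rate before correction (default 0.05).
#' @return A list with `pairs` (data frame: `snp1`, `snp2`, `beta_int`,
#'   `se_int`, `p_int`, `significant`), `threshold`, and `skipped`
#'   (monomorphic-pair log).
#' @export
epistasis_scan <- function(G, pheno, trait, snps, covariates = NULL,
                           alpha = 0.05) {
  if (length(snps) < 2) stop("need at least 2 SNPs")
  if (is.null(covariates))
    covariates <- intersect(c("age", "sex", paste0("PC", 1:6)), names(pheno))
  keep <- stats::complete.cases(pheno[c(trait, covariates)])
  X <- .assoc_design(G[keep, , drop = FALSE], pheno[keep, , drop = FALSE],
                     covariates, character())
  y <- as.numeric(pheno[[trait]][keep])
  thr <- alpha / choose(length(snps), 2)
  prs <- utils::combn(snps, 2)
  skipped <- character()
  rows <- lapply(seq_len(ncol(prs)), function(j) {
    s1 <- prs[1, j]; s2 <- prs[2, j]
    g1 <- G[keep, s1]; g2 <- G[keep, s2]
    if (stats::var(g1) == 0 || stats::var(g2) == 0) {
      skipped <<- c(skipped, paste0(s1, ":", s2))
      return(NULL)
    }
    r <- .ols_term(y, cbind(X, g1 = g1, g2 = g2), g1 * g2)
    data.frame(snp1 = s1, snp2 = s2, beta_int = r[["beta"]],
               se_int = r[["se"]], p_int = r[["p"]])
  })
  rows <- do.call(rbind, rows)
  if (!is.null(rows)) rows$significant <- rows$p_int < thr
  if (length(skipped))
    message("epistasis_scan: skipped monomorphic pairs: ",
            paste(skipped, collapse = ", "))
  list(pairs = rows, threshold = thr, skipped = skipped)
}

#' Multivariate Wald test of a SNP against all phenotypes
#'
#' Reverse regression: the SNP dosage is the response and all phenotypes are
#' joint predictors (plus age/sex/PC covariates); the Wald chi-square tests
#' that the phenotype coefficients are jointly zero, with df = number of
#' phenotypes. Exploits the correlation between pigmentation traits to gain
#' power for SNPs with effects across several of them.
#'
#' @param g numeric dosage vector.
#' @param phenotypes matrix or data frame of phenotype columns (full rank).
#' @param covariate_data optional data frame of covariates.
#' @param covariates covariate column names within `covariate_data`.
#' @return A list with `wald` (chi-square statistic), `df`, and `p`.
#' @export
multivariate_wald <- function(g, phenotypes, covariate_data = NULL,
                              covariates = NULL) {
  P <- as.matrix(phenotypes)
  if (qr(scale(P, scale = FALSE))$rank < ncol(P))
    stop("phenotype block is rank deficient")
  X <- matrix(1, nrow(P), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariate_data)) {
    if (is.null(covariates))
      covariates <- intersect(c("age", "sex", paste0("PC", 1:6)),
                              names(covariate_data))
    X <- cbind(X, as.matrix(covariate_data[covariates]))
  }
  D <- cbind(X, P)
  fit <- stats::lm.fit(D, as.numeric(g))
  if (anyNA(fit$coefficients))
    stop("design is rank deficient")
  df_res <- length(g) - fit$rank
  sigma2 <- sum(fit$residuals^2) / df_res
  piv <- fit$qr$pivot[seq_len(fit$rank)]
  R <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
  idx <- match((ncol(X) + 1):ncol(D), piv)   # phenotype block, pivot-safe
  b <- fit$coefficients[(ncol(X) + 1):ncol(D)]
  V <- sigma2 * R[idx, idx, drop = FALSE]
  W <- as.numeric(t(b) %*% solve(V, b))
  list(wald = W, df = ncol(P),
       p = stats::pchisq(W, df = ncol(P), lower.tail = FALSE))
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-stratum (e.g. per-country) regression coefficients with weights
#' `1/SE^2`; the pooled z statistic gives the meta-analytic P value.
#'
#' @param betas numeric vector of per-stratum coefficients.
#' @param ses matching standard errors (> 0; `Inf` gives a zero weight).
#' @return A list with `beta`, `se`, `z`, `p`, `n_strata`.
#' @export
meta_analyze <- function(betas, ses) {
  stopifnot(length(betas) == length(ses), all(ses > 0))
  if (length(betas) < 2) {
    warning("single stratum: returning it unchanged")
    return(list(beta = betas, se = ses, z = betas / ses,
                p = 2 * stats::pnorm(-abs(betas / ses)), n_strata = 1L))
  }
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- beta / se
  list(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       n_strata = length(betas))
}

#' Tail strength of a genome-wide P value set
#'
#' A polygenicity measure over the ordered P values
#' `p_(1) <= ... <= p_(n)`:
#' `TS = (1/n) * sum_k (1 - p_(k) * (n + 1) / k)`.
#' TS is 0 under the global null (uniform P values), positive when the P
#' value distribution is shifted toward small values across the genome, and
#' bounded above by 1. Its asymptotic SD is `1/sqrt(n_star)`, where `n_star`
#' is the effective number of independent SNPs (after LD pruning).
#'
#' @param p P values in `(0, 1]`.
#' @param n_star effective number of independent SNPs used for the SD (and
#'   the +/- 3 SD band); defaults to `length(p)`.
#' @return A list with `TS`, `TS_sd`, `band_halfwidth` (3 * SD), `n`,
#'   `n_star`.
#' @examples
#' tail_strength(c(0.01, 0.2, 0.5, 0.9))$TS
#' @export
tail_strength <- function(p, n_star = length(p)) {
  if (!length(p)) stop("empty P value vector")
  if (any(p <= 0 | p > 1)) stop("P values must lie in (0, 1]")
  n <- length(p)
  ps <- sort(p)
  TS <- mean(1 - ps * (n + 1) / seq_len(n))
  sd <- 1 / sqrt(n_star)
  list(TS = TS, TS_sd = sd, band_halfwidth = 3 * sd, n = n, n_star = n_star)
}

#' Genomic inflation factor
#'
#' `lambda = median(chi^2) / qchisq(0.5, 1)`: the ratio of the observed
#' median association chi-square to the null median (0.4549...). Values far
#' above 1 indicate residual stratification or high polygenicity.
#'
#' @param chisq nonnegative chi-square statistics (1 df).
#' @return A single number.
#' @export
genomic_inflation <- function(chisq) {
  if (!length(chisq)) stop("empty statistic vector")
  if (any(chisq < 0)) stop("chi-square statistics must be nonnegative")
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}
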