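# Two-SNP haplotype frequency EM from unphased genotype dosages (0/1/2).
# Returns MLE haplotype frequencies (pAB, pAb, paB, pab) for alleles coded
# by the dosage (A = allele counted by g1, etc.).
.hap_freq_em <- function(g1, g2, max_iter = 100, tol = 1e-10) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  p1 <- mean(g1) / 2; p2 <- mean(g2) / 2
  # counts of the 9 genotype combinations
  tab <- table(factor(g1, 0:2), factor(g2, 0:2))
  f <- c(AB = p1 * p2, Ab = p1 * (1 - p2), aB = (1 - p1) * p2,
         ab = (1 - p1) * (1 - p2))
  ndh <- tab["1", "1"]  # double heterozygotes: phase-ambiguous
  for (it in seq_len(max_iter)) {
    # expected fraction of double hets that are AB/ab
    denom <- f["AB"] * f["ab"] + f["Ab"] * f["aB"]
    w <- if (denom > 0) f["AB"] * f["ab"] / denom else 0.5
    nAB <- 2 * tab["2", "2"] + tab["2", "1"] + tab["1", "2"] + w * ndh
    nAb <- 2 * tab["2", "0"] + tab["2", "1"] + tab["1", "0"] + (1 - w) * ndh
    naB <- 2 * tab["0", "2"] + tab["1", "2"] + tab["0", "1"] + (1 - w) * ndh
    nab <- 2 * tab["0", "0"] + tab["0", "1"] + tab["1", "0"] + w * ndh
    f_new <- c(nAB, nAb, naB, nab) / (2 * n)
    names(f_new) <- names(f)
    if (max(abs(f_new - f)) < tol) { f <- f_new; break }
    f <- f_new
  }
  f
}

# Likelihood-profile confidence bounds on |D'| for a SNP pair, following the
# Gabriel et al. scheme: profile the multinomial likelihood over D' with
# allele frequencies fixed at their MLEs, normalize to a posterior over a
# 0..1 grid, and report the 5th/95th percentiles.
.dprime_ci <- function(g1, g2, grid = seq(0, 1, by = 0.005)) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  f <- .hap_freq_em(g1, g2)
  p1 <- f["AB"] + f["Ab"]; p2 <- f["AB"] + f["aB"]
  D <- f["AB"] - p1 * p2
  sign_d <- if (D >= 0) 1 else -1
  dmax <- if (D >= 0) min(p1 * (1 - p2), (1 - p1) * p2)
          else min(p1 * p2, (1 - p1) * (1 - p2))
  if (dmax <= 0) return(list(dprime = 0, lo = 0, hi = 1))
  tab <- table(factor(g1, 0:2), factor(g2, 0:2))
  # enumerate, once, the gamete pairs consistent with each genotype cell
  gam <- expand.grid(a = 0:1, b = 0:1, c = 0:1, d = 0:1)
  combos <- lapply(0:2, function(i) lapply(0:2, function(j) {
    g <- gam[gam$a + gam$c == i & gam$b + gam$d == j, , drop = FALSE]
    cbind(g$a * 2 + g$b + 1, g$c * 2 + g$d + 1)  # hap indices ab,aB,Ab,AB
  }))
  loglik <- vapply(grid, function(dp) {
    Dg <- sign_d * dp * dmax
    h <- pmax(c(ab = (1 - p1) * (1 - p2) + Dg, aB = (1 - p1) * p2 - Dg,
                Ab = p1 * (1 - p2) - Dg, AB = p1 * p2 + Dg), 1e-12)
    ll <- 0
    for (i in 0:2) for (j in 0:2) {
      nij <- tab[i + 1, j + 1]
      if (nij == 0) next
      cmb <- combos[[i + 1]][[j + 1]]
      pr <- sum(h[cmb[, 1]] * h[cmb[, 2]])
      ll <- ll + nij * log(max(pr, 1e-300))
    }
    ll
  }, numeric(1))
  post <- exp(loglik - max(loglik))
  post <- post / sum(post)
  cdf <- cumsum(post)
  list(dprime = abs(D) / dmax,
       lo = grid[which(cdf >= 0.05)[1]],
       hi = grid[which(cdf >= 0.95)[1]])
}

#' Haplotype blocks by the confidence-interval (Gabriel) rule
#'
#' Classifies SNP pairs from the likelihood-based confidence interval on
#' |D'|: "strong LD" if the lower bound is at least `strong_lo` and the
#' upper at least `strong_hi`; "strong recombination" if the upper bound is
#' below `recomb_hi`. A candidate block is an interval whose outermost pair
#' is in strong LD and in which at least `informative_frac` of informative
#' pairs are strong-LD; candidates are accepted longest-first without
#' overlap. Pairs farther apart than `max_pair_bp` are never considered.
#'
#' @param G dosage matrix (individuals x SNPs, 0/1/2; phased data can be
#'   supplied as dosages of haplotype pairs).
#' @param positions physical positions (bp).
#' @param max_pair_bp maximum pair distance (default 5e5).
#' @param strong_lo,strong_hi,recomb_hi CI thresholds (defaults 0.70, 0.98,
#'   0.90, the PLINK/Haploview defaults).
#' @param informative_frac minimum fraction of informative pairs in strong
#'   LD (default 0.95).
#' @param min_snps blocks with fewer SNPs are dropped (default 5, matching
#'   the downstream enrichment rule; set to 2 to keep all).
#' @return A data frame of blocks: `start_bp`, `end_bp` (closed interval),
#'   `first_snp`, `last_snp` (column indices), `n_snps`. Fewer than 2 SNPs
#'   gives an empty result.
#' @export
haplotype_blocks <- function(G, positions, max_pair_bp = 5e5,
                             strong_lo = 0.70, strong_hi = 0.98,
                             recomb_hi = 0.90, informative_frac = 0.95,
                             min_snps = 5L) {
  G <- as.matrix(G)
  m <- ncol(G)
  empty <- data.frame(start_bp = numeric(), end_bp = numeric(),
                      first_snp = integer(), last_snp = integer(),
                      n_snps = integer())
  if (m < 2) return(empty)
  stopifnot(length(positions) == m)
  # pair classification: 1 strong LD, -1 strong recomb, 0 uninformative
  cls <- matrix(NA_integer_, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (positions[j] - positions[i] > max_pair_bp) { cls[i, j] <- NA; next }
    if (stats::var(G[, i]) == 0 || stats::var(G[, j]) == 0) { cls[i, j] <- 0L; next }
    ci <- .dprime_ci(G[, i], G[, j])
    cls[i, j] <- if (ci$lo >= strong_lo && ci$hi >= strong_hi) 1L
                 else if (ci$hi < recomb_hi) -1L else 0L
  }
  # candidate blocks: outermost pair strong LD, informative-pair rule
  cand <- list()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (is.na(cls[i, j]) || cls[i, j] != 1L) next
    sub <- cls[i:j, i:j]
    vals <- sub[upper.tri(sub)]
    inf <- vals[!is.na(vals) & vals != 0L]
    if (!length(inf) || mean(inf == 1L) < informative_frac) next
    cand[[length(cand) + 1]] <- c(i = i, j = j)
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  ord <- order(positions[cand[, "j"]] - positions[cand[, "i"]],
               decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  used <- rep(FALSE, m)
  out <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, "i"]; j <- cand[r, "j"]
    if (any(used[i:j])) next
    used[i:j] <- TRUE
    out[[length(out) + 1]] <- data.frame(
      start_bp = positions[i], end_bp = positions[j],
      first_snp = i, last_snp = j, n_snps = j - i + 1L)
  }
  out <- do.call(rbind, out)
  out <- out[out$n_snps >= min_snps, , drop = FALSE]
  out <- out[order(out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Selection-score enrichment at associated haplotype blocks
#'
#' Contrasts the per-block maximum selection scores (PBS or |iHS|) of
#' blocks containing association signals with those of the rest of the
#' genome, using a one-sided Mann--Whitney U test (alternative: associated
#' blocks have larger maxima).
#'
#' @param assoc_scores per-block maximum scores for blocks containing
#'   associated SNPs (nonempty).
#' @param background_scores per-block maxima for the remaining blocks
#'   (nonempty).
#' @param exact use the exact null distribution (default `FALSE`: normal
#'   approximation with tie correction, as for genome-scale block sets).
#' @return A list with `U` (statistic for the associated group) and `p`.
#' @export
block_enrichment <- function(assoc_scores, background_scores, exact = FALSE) {
  if (!length(assoc_scores) || !length(background_scores))
    stop("both block groups must be nonempty")
  wt <- stats::wilcox.test(assoc_scores, background_scores,
                           alternative = "greater", exact = exact,
                           correct = !exact)
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Per-block maximum scores
#'
#' Assigns per-SNP scores to blocks by position and returns each block's
#' maximum, with a flag for blocks containing associated SNPs.
#'
#' @param blocks data frame from [haplotype_blocks].
#' @param score_pos positions of scored SNPs.
#' @param scores per-SNP scores.
#' @param assoc_pos positions of associated SNPs (association P below the
#'   suggestive threshold).
#' @return `blocks` with added `max_score` and `associated` columns (blocks
#'   with no scored SNP are dropped).
#' @export
block_max_scores <- function(blocks, score_pos, scores, assoc_pos = numeric()) {
  rows <- lapply(seq_len(nrow(blocks)), function(b) {
    sel <- score_pos >= blocks$start_bp[b] & score_pos <= blocks$end_bp[b]
    if (!any(sel)) return(NULL)
    cbind(blocks[b, , drop = FALSE],
          max_score = max(scores[sel]),
          associated = any(assoc_pos >= blocks$start_bp[b] &
                             assoc_pos <= blocks$end_bp[b]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
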