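# Shared fixtures and independent oracles used across test files.

# tiny deterministic haplotype panel
toy_panel <- function(H, positions = NULL, rate_cM_Mb = 1) {
  H <- as.matrix(H)
  if (is.null(positions)) positions <- seq_len(ncol(H)) * 1000
  haplotype_panel(H, positions, rate_cM_Mb = rate_cM_Mb)
}

# brute-force EHH: probability that two random haplotypes of the core
# allele class are identical over the SNP interval between core and j
oracle_ehh <- function(H, core, allele, j) {
  cls <- which(H[, core] == allele)
  rng <- sort(c(core, j))
  seg <- H[cls, rng[1]:rng[2], drop = FALSE]
  n <- length(cls)
  same <- 0
  for (a in seq_len(n - 1)) for (b in (a + 1):n)
    if (all(seg[a, ] == seg[b, ])) same <- same + 1
  same / choose(n, 2)
}

# brute-force trapezoid iHH for one side with truncation rules
oracle_ihh_side <- function(panel, core, allele, side, cutoff = 0.05,
                            max_bp = 1e6) {
  cols <- if (side == "left") rev(seq_len(core)) else core:ncol(panel$H)
  x <- c(); y <- c()
  for (j in cols) {
    if (abs(panel$positions[j] - panel$positions[core]) > max_bp) break
    e <- oracle_ehh(panel$H, core, allele, j)
    x <- c(x, abs(panel$cM[j] - panel$cM[core]))
    y <- c(y, e)
    if (e < cutoff) break
  }
  decayed <- length(y) > 0 && y[length(y)] < cutoff
  ihh <- if (length(y) > 1)
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2) else 0
  list(ihh = ihh, decayed = decayed)
}

# textbook Tajima's D from S, pi, n (coded independently of the package)
oracle_tajima_d <- function(S, pi, n) {
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# plain Hudson coalescent (no recombination): returns derived allele counts
# of segregating sites for n sampled haplotypes under theta
oracle_coalescent_sfs <- function(n, theta) {
  # lineages: list of tip sets; branch lengths accumulate waiting times
  members <- as.list(seq_len(n))
  counts <- integer(0)
  k <- n
  while (k > 1) {
    t_wait <- rexp(1, k * (k - 1) / 2)
    # mutations fall on each of k branches for duration t_wait
    nmut <- rpois(k, theta / 2 * t_wait)
    for (i in seq_len(k)) if (nmut[i] > 0)
      counts <- c(counts, rep(length(members[[i]]), nmut[i]))
    pair <- sample.int(k, 2)
    members[[pair[1]]] <- c(members[[pair[1]]], members[[pair[2]]])
    members[[pair[2]]] <- NULL
    k <- k - 1
  }
  counts[counts < n]
}

# turn derived-allele counts into a haplotype matrix with random assignment
sfs_to_matrix <- function(n, counts) {
  if (!length(counts)) return(matrix(0L, n, 0))
  H <- matrix(0L, n, length(counts))
  for (j in seq_along(counts)) H[sample.int(n, counts[j]), j] <- 1L
  H
}

# small admixed cohort for association tests
quick_cohort <- function(n = 400, m = 60, causal = NULL, h2 = 0.5,
                         seed = 42) {
  generate_admixed_cohort(cohort_spec(n, m, causal_snps = causal,
                                      trait_heritability = h2, seed = seed))
}
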