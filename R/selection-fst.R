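#' Reynolds-model FST from allele counts
#'
#' Coancestry (FST) estimator in the Reynolds, Weir & Cockerham (1983)
#' framework: populations drift independently from a common ancestor, and
#' the estimator corrects the squared frequency difference for binomial
#' sampling so that it is unbiased for the between-population component.
#' Per SNP, with sample frequencies `p1, p2` from `n1, n2` sampled alleles:
#' \deqn{a = (p1-p2)^2 - p1 q1/(n1-1) - p2 q2/(n2-1)}
#' \deqn{b = n1 p1 q1/(n1-1) + n2 p2 q2/(n2-1)}
#' and `FST = a / (a + b)`. The estimate may be slightly negative for
#' undifferentiated populations. The multi-SNP estimate is the ratio of
#' summed numerators over summed denominators.
#'
#' @param counts_a,counts_b per-population allele counts: either a length-2
#'   vector `c(derived, total)` for one SNP, or a 2-column matrix (rows =
#'   SNPs) of derived and total counts.
#' @param per_snp if `TRUE` return the per-SNP estimates instead of the
#'   ratio-of-sums.
#' @return FST estimate(s).
#' @examples
#' reynolds_fst(c(90, 100), c(10, 100))
#' @export
reynolds_fst <- function(counts_a, counts_b, per_snp = FALSE) {
  ca <- if (is.matrix(counts_a)) counts_a else matrix(counts_a, 1)
  cb <- if (is.matrix(counts_b)) counts_b else matrix(counts_b, 1)
  stopifnot(ncol(ca) == 2, ncol(cb) == 2, nrow(ca) == nrow(cb))
  if (any(ca[, 2] < 1) || any(cb[, 2] < 1)) stop("zero sample size")
  n1 <- ca[, 2]; n2 <- cb[, 2]
  p1 <- ca[, 1] / n1; p2 <- cb[, 1] / n2
  poly <- (p1 > 0 & p1 < 1) | (p2 > 0 & p2 < 1) | (p1 != p2)
  h1 <- p1 * (1 - p1) / pmax(n1 - 1, 1)
  h2 <- p2 * (1 - p2) / pmax(n2 - 1, 1)
  a <- (p1 - p2)^2 - h1 - h2
  b <- n1 * h1 + n2 * h2
  if (per_snp) {
    fst <- a / (a + b)
    fst[!poly] <- NA_real_   # monomorphic for the same allele: undefined
    return(as.vector(fst))
  }
  if (!any(poly)) stop("SNP(s) monomorphic in both populations")
  sum(a[poly]) / sum(a[poly] + b[poly])
}

#' Population branch statistic
#'
#' Allocates allele-frequency divergence to the branch of a focal
#' population using two references: with `T = -log(1 - FST)` for each
#' population pair,
#' `PBS = (T_f1 + T_f2 - T_12) / 2`.
#' Large values indicate lineage-specific drift or a sweep in the focal
#' population since its split from the references. Negative FST estimates
#' are truncated at 0 before the log transform (the raw FSTs are returned
#' untruncated).
#'
#' @param focal,ref1,ref2 allele counts as in [reynolds_fst] (length-2
#'   vector per SNP or 2-column matrices).
#' @return A list with `pbs` (numeric vector), and `fst` (3-column matrix of
#'   the raw pairwise estimates focal-ref1, focal-ref2, ref1-ref2). A pair
#'   with FST = 1 yields `Inf` with a warning.
#' @export
pbs <- function(focal, ref1, ref2) {
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, 1)
  focal <- as_mat(focal); ref1 <- as_mat(ref1); ref2 <- as_mat(ref2)
  f01 <- reynolds_fst(focal, ref1, per_snp = TRUE)
  f02 <- reynolds_fst(focal, ref2, per_snp = TRUE)
  f12 <- reynolds_fst(ref1, ref2, per_snp = TRUE)
  Tof <- function(f) {
    f[is.na(f)] <- 0  # pair monomorphic for the same allele: no divergence
    -log(1 - pmin(pmax(f, 0), 1))
  }
  if (any(c(f01, f02) >= 1, na.rm = TRUE))
    warning("FST = 1 encountered; PBS reported as Inf")
  score <- (Tof(f01) + Tof(f02) - Tof(f12)) / 2
  score[is.na(f01) & is.na(f02) & is.na(f12)] <- NA_real_
  list(pbs = as.vector(score),
       fst = cbind(focal_ref1 = f01, focal_ref2 = f02, ref1_ref2 = f12))
}

#' Per-SNP allele counts for PBS across populations
#'
#' Convenience helper turning per-population haplotype panels (sharing SNP
#' columns) into the count matrices [pbs] consumes. A SNP is kept when it
#' is polymorphic across at least two populations considered jointly (a
#' fixed difference between two populations counts: that is the
#' configuration where FST, and the classic sweep signature, is largest).
#'
#' @param panels named list of [haplotype_panel]s with identical SNP sets.
#' @return A list of 2-column count matrices plus the retained SNP index.
#' @export
panel_counts <- function(panels) {
  H <- lapply(panels, function(p) p$H)
  m <- ncol(H[[1]])
  counts <- lapply(H, function(h) cbind(colSums(h), nrow(h)))
  # pooled polymorphism over every population pair
  pairs <- utils::combn(length(counts), 2)
  pair_poly <- sapply(seq_len(ncol(pairs)), function(k) {
    a <- counts[[pairs[1, k]]]; b <- counts[[pairs[2, k]]]
    d <- a[, 1] + b[, 1]
    d > 0 & d < a[, 2] + b[, 2]
  })
  keep <- rowSums(pair_poly) >= 2
  list(counts = lapply(counts, function(cc) cc[keep, , drop = FALSE]),
       keep = which(keep))
}
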