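#' Site-frequency-spectrum summary statistics
#'
#' Internal building blocks shared by the windowed Tajima's D scan and the
#' sweep-inference summaries: nucleotide diversity, Watterson's theta,
#' Tajima's D, and Fu & Li's D and F (which contrast derived singletons,
#' counted using ancestral-state polarity, with the other estimators of
#' theta).
#'
#' @param H 0/1 haplotype matrix (haplotypes x SNPs, 1 = derived); columns
#'   should be segregating sites.
#' @return `site_stats` returns a list with `n` (haplotypes), `S`
#'   (segregating sites), `pi` (mean pairwise differences), `singletons`
#'   (derived singleton count), `tajimas_d`, `fu_li_d`, `fu_li_f`.
#' @export
site_stats <- function(H) {
  H <- as.matrix(H)
  n <- nrow(H)
  if (n < 4) stop("need at least 4 haplotypes for the variance terms")
  dac <- colSums(H)
  seg <- dac > 0 & dac < n
  dac <- dac[seg]
  S <- length(dac)
  pi <- if (S) sum(dac * (n - dac)) / choose(n, 2) else 0
  eta_s <- sum(dac == 1)
  list(n = n, S = S, pi = pi, singletons = eta_s,
       tajimas_d = .tajima_d_from(S, pi, n),
       fu_li_d = .fu_li_d_from(S, eta_s, n),
       fu_li_f = .fu_li_f_from(S, pi, eta_s, n))
}

.harmonic <- function(n) sum(1 / seq_len(n))

.tajima_d_from <- function(S, pi, n) {
  if (S == 0) return(NA_real_)
  a1 <- .harmonic(n - 1)
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Fu & Li (1993) D, with eta = S total mutations and eta_s derived singletons
.fu_li_d_from <- function(S, eta_s, n) {
  if (S == 0) return(NA_real_)
  a <- .harmonic(n - 1)
  b <- sum(1 / seq_len(n - 1)^2)
  c <- if (n == 2) 1 else 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + a^2 / (b + a^2) * (c - (n + 1) / (n - 1))
  uD <- a - 1 - vD
  (S - a * eta_s) / sqrt(uD * S + vD * S^2)
}

.fu_li_f_from <- function(S, pi, eta_s, n) {
  if (S == 0) return(NA_real_)
  a <- .harmonic(n - 1)
  an1 <- a + 1 / n
  b <- sum(1 / seq_len(n - 1)^2)
  c <- if (n == 2) 1 else 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vF <- (c + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) / (a^2 + b)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
           4 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a - vF
  (pi - eta_s) / sqrt(uF * S + vF * S^2)
}

#' Windowed Tajima's D scan
#'
#' Tajima's D in non-overlapping windows tiling the region (half-open
#' `[start, start + window)`); windows with fewer than `min_snps`
#' segregating sites are discarded. Negative values indicate an excess of
#' rare variants, as after a sweep or expansion.
#'
#' @param panel a [haplotype_panel] (>= 4 haplotypes).
#' @param window window size in bp (default 10000).
#' @param min_snps minimum segregating sites per retained window (default 5).
#' @param start first window start (default 1).
#' @return Data frame with `start`, `end` (half-open bounds), `n_snps`, `D`.
#' @export
tajimas_d <- function(panel, window = 10000, min_snps = 5, start = 1) {
  if (nrow(panel$H) < 4) stop("need at least 4 haplotypes")
  pos <- panel$positions
  idx <- floor((pos - start) / window)
  out <- lapply(sort(unique(idx)), function(w) {
    sel <- idx == w
    if (sum(sel) < min_snps) return(NULL)
    st <- site_stats(panel$H[, sel, drop = FALSE])
    if (st$S < min_snps) return(NULL)
    data.frame(start = start + w * window, end = start + (w + 1) * window,
               n_snps = st$S, D = st$tajimas_d)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(start = numeric(), end = numeric(),
                      n_snps = integer(), D = numeric())
  out
}

#' Garud's haplotype homozygosity statistics
#'
#' With haplotype frequencies `p_1 >= p_2 >= ...` in a window:
#' `H1 = sum p_i^2`, `H2 = H1 - p_1^2`, and `H2/H1`. Hard sweeps drive H1 up
#' and H2/H1 down; soft sweeps keep H2/H1 comparatively high.
#'
#' @param H 0/1 haplotype matrix over the window.
#' @return A list with `h1`, `h2`, `h2_h1`.
#' @export
garud_h <- function(H) {
  H <- as.matrix(H)
  key <- apply(H, 1, paste, collapse = "")
  p <- sort(as.vector(table(key)) / nrow(H), decreasing = TRUE)
  h1 <- sum(p^2)
  h2 <- h1 - p[1]^2
  list(h1 = h1, h2 = h2, h2_h1 = if (h1 > 0) h2 / h1 else 0)
}

#' Genome-wide empirical P values
#'
#' Outlier-style P values: each score's rank from the relevant tail divided
#' by the number of scores (minimum `1/n`); ties share the worst (largest)
#' rank. Upper tail for PBS and iHS (large = candidate sweep), lower tail
#' for Tajima's D.
#'
#' @param scores numeric vector.
#' @param tail `"upper"` or `"lower"`.
#' @return Empirical P values in `(0, 1]`, same order as `scores`.
#' @examples
#' empirical_p(c(5, 3, 3, 1), "upper")  # 0.25 0.75 0.75 1
#' @export
empirical_p <- function(scores, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (!length(scores)) stop("empty score vector")
  n <- length(scores)
  cnt <- if (tail == "upper") n - rank(scores, ties.method = "min") + 1
         else rank(scores, ties.method = "max")
  cnt / n
}
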