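# Walk outward from the core on one side, computing EHH at each SNP for the
# haplotype class carrying `allele` at the core. Stops early once EHH drops
# below `stop_below` or the walk leaves `max_bp` of the core.
.ehh_walk <- function(panel, core, allele, side, stop_below = 0, max_bp = Inf) {
  H <- panel$H
  cls <- which(H[, core] == allele)
  if (length(cls) < 2)
    stop("core allele class has fewer than 2 haplotypes; EHH undefined")
  sub <- H[cls, , drop = FALSE]
  n <- length(cls)
  denom <- choose(n, 2)
  cols <- if (side == "left") rev(seq_len(core)) else core:ncol(H)
  grp <- rep(1L, n)
  snps <- integer(0); vals <- numeric(0)
  for (j in cols) {
    if (abs(panel$positions[j] - panel$positions[core]) > max_bp) break
    key <- grp * 2L + sub[, j]
    grp <- match(key, unique(key))
    e <- sum(choose(tabulate(grp), 2)) / denom
    snps <- c(snps, j); vals <- c(vals, e)
    if (e < stop_below) break
  }
  data.frame(snp = snps, position = panel$positions[snps],
             cM = panel$cM[snps], ehh = vals)
}

#' Extended haplotype homozygosity around a core SNP
#'
#' For the haplotypes carrying a given core allele, EHH at a SNP is the
#' probability that two haplotypes drawn at random from that class are
#' identical at every SNP between the core and that SNP (inclusive):
#' `EHH(x) = sum_h C(n_h, 2) / C(n_class, 2)` over the counts `n_h` of the
#' distinct extended haplotypes. EHH equals 1 at the core and is
#' non-increasing outward; long-range EHH on the derived background is the
#' signature of a recent incomplete sweep.
#'
#' @param panel a [haplotype_panel].
#' @param core core SNP column index.
#' @param allele 1 for the derived class, 0 for the ancestral class.
#' @param direction `"both"` (default, ordered by position, core appearing
#'   once), `"left"` or `"right"` (ordered outward from the core).
#' @return A data frame with `snp` (column index), `position`, `cM`, `ehh`.
#'   A singleton or empty core allele class is an error.
#' @export
ehh <- function(panel, core, allele = 1L,
                direction = c("both", "left", "right")) {
  direction <- match.arg(direction)
  switch(direction,
    left = .ehh_walk(panel, core, allele, "left"),
    right = .ehh_walk(panel, core, allele, "right"),
    both = {
      l <- .ehh_walk(panel, core, allele, "left")
      r <- .ehh_walk(panel, core, allele, "right")
      l <- l[nrow(l):1, , drop = FALSE]
      out <- rbind(l[-nrow(l), , drop = FALSE], r)
      rownames(out) <- NULL
      out
    })
}

# Integrated EHH (trapezoid over cM) for one allele class on one side,
# truncated at the first EHH < cutoff or at max_bp from the core.
# decayed = FALSE flags a side whose EHH never fell below the cutoff.
.ihh_side <- function(panel, core, allele, side, cutoff = 0.05, max_bp = 1e6) {
  e <- .ehh_walk(panel, core, allele, side, stop_below = cutoff,
                 max_bp = max_bp)
  decayed <- nrow(e) > 0 && e$ehh[nrow(e)] < cutoff
  x <- abs(e$cM - e$cM[1])
  y <- e$ehh
  ihh <- if (nrow(e) > 1)
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) else 0
  list(ihh = ihh, decayed = decayed)
}

#' Integrated haplotype score scan
#'
#' For each core SNP passing the filters, integrates EHH over genetic
#' distance on both sides for the ancestral and derived allele classes
#' (trapezoid rule, truncated where EHH < `cutoff` or at `max_bp` from the
#' core), forms the unstandardized score `ln(iHH_A / iHH_D)`, and
#' standardizes within derived-allele-frequency bins to mean 0 and SD 1.
#'
#' Filters: SNPs with derived allele frequency outside (`maf`, 1 - `maf`)
#' are skipped, and SNPs whose EHH (either allele class) has not decayed
#' below `cutoff` within `max_bp` are excluded (absent from the output, not
#' `NA`).
#'
#' @param panel a [haplotype_panel].
#' @param maf frequency filter bound (default 0.05).
#' @param cutoff EHH truncation level (default 0.05).
#' @param max_bp physical truncation distance per side (default 1e6).
#' @param bin_width derived-allele-frequency bin width for standardization
#'   (default 0.02, i.e. 50 bins).
#' @param standardize set `FALSE` to return unstandardized scores only.
#' @param snps optional subset of core SNP column indices to scan.
#' @return Data frame with `snp` (column index), `snp_id`, `position`,
#'   `daf`, `ihh_a`, `ihh_d`, `ihs_unstd` and (if standardizing) `ihs`;
#'   `NULL` if no SNP passes the filters.
#' @export
ihs <- function(panel, maf = 0.05, cutoff = 0.05, max_bp = 1e6,
                bin_width = 0.02, standardize = TRUE, snps = NULL) {
  H <- panel$H
  daf <- colMeans(H)
  if (is.null(snps)) snps <- seq_len(ncol(H))
  rows <- lapply(snps, function(j) {
    if (daf[j] <= maf || daf[j] >= 1 - maf) return(NULL)
    sides <- tryCatch(
      lapply(c("left", "right"), function(sd_) {
        list(a = .ihh_side(panel, j, 0L, sd_, cutoff, max_bp),
             d = .ihh_side(panel, j, 1L, sd_, cutoff, max_bp))
      }),
      error = function(e) NULL)  # singleton allele class: skip the SNP
    if (is.null(sides)) return(NULL)
    if (!all(vapply(sides, function(s) s$a$decayed && s$d$decayed,
                    logical(1))))
      return(NULL)
    ihh_a <- sum(vapply(sides, function(s) s$a$ihh, numeric(1)))
    ihh_d <- sum(vapply(sides, function(s) s$d$ihh, numeric(1)))
    if (ihh_a <= 0 || ihh_d <= 0) return(NULL)
    data.frame(snp = j, snp_id = panel$snp_ids[j],
               position = panel$positions[j], daf = daf[j],
               ihh_a = ihh_a, ihh_d = ihh_d,
               ihs_unstd = log(ihh_a / ihh_d))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  if (standardize) {
    bin <- pmin(floor(out$daf / bin_width), round(1 / bin_width) - 1)
    out$ihs <- out$ihs_unstd
    for (b in unique(bin)) {
      i <- bin == b
      mu <- mean(out$ihs_unstd[i])
      sdv <- stats::sd(out$ihs_unstd[i])
      out$ihs[i] <- if (is.na(sdv) || sdv == 0) 0
                    else (out$ihs_unstd[i] - mu) / sdv
    }
  }
  rownames(out) <- NULL
  out
}
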