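#' Construct a phased haplotype panel
#'
#' A binary haplotype matrix (rows = haplotypes, columns = SNPs, 1 = derived
#' allele) with physical and genetic positions. Ancestral/derived polarity
#' is assumed already resolved (e.g. from an ancestral-allele INFO tag).
#'
#' @param H 0/1 matrix, haplotypes in rows.
#' @param positions physical positions in bp (1-based, strictly increasing).
#' @param cM genetic map positions (non-decreasing); if `NULL`, computed
#'   from a uniform rate via `rate_cM_Mb`.
#' @param rate_cM_Mb uniform recombination rate used when `cM` is missing
#'   (default 1 cM/Mb).
#' @param snp_ids optional SNP identifiers.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(H, positions, cM = NULL, rate_cM_Mb = 1,
                            snp_ids = NULL) {
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  if (!all(H %in% c(0L, 1L))) stop("haplotype entries must be 0/1")
  positions <- as.numeric(positions)
  if (length(positions) != ncol(H))
    stop("positions must match the number of SNPs")
  if (is.unsorted(positions, strictly = TRUE))
    stop("physical positions must be strictly increasing")
  if (is.null(cM)) cM <- positions / 1e6 * rate_cM_Mb
  if (length(cM) != ncol(H) || is.unsorted(cM))
    stop("genetic positions must be non-decreasing and match the SNPs")
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(H)))
  structure(list(H = H, positions = positions, cM = as.numeric(cM),
                 snp_ids = as.character(snp_ids)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", nrow(x$H), " haplotypes x ", ncol(x$H),
      " SNPs, span ", round(diff(range(x$positions)) / 1000, 1), " kb\n",
      sep = "")
  invisible(x)
}

#' Derived allele frequencies of a panel
#' @param panel a [haplotype_panel].
#' @return Numeric vector of per-SNP derived allele frequencies.
#' @export
derived_freq <- function(panel) colMeans(panel$H)

#' Write a haplotype panel as a phased VCF
#'
#' Minimal uncompressed VCF4.2 writer with the ancestral allele recorded in
#' the `AA` INFO field (REF is written as the ancestral allele, ALT as the
#' derived allele). Consecutive haplotype pairs form diploid samples.
#'
#' @param panel a [haplotype_panel] with an even number of haplotypes.
#' @param path output file path.
#' @param chrom chromosome label.
#' @export
write_panel_vcf <- function(panel, path, chrom = "1") {
  H <- panel$H
  if (nrow(H) %% 2L) stop("need an even number of haplotypes for diploid VCF")
  ns <- nrow(H) / 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", paste0("S", seq_len(ns))),
                     collapse = "\t")), con)
  gt <- matrix(paste(H[seq(1, nrow(H), 2), , drop = FALSE],
                     H[seq(2, nrow(H), 2), , drop = FALSE], sep = "|"),
               nrow = ns)
  for (j in seq_len(ncol(H)))
    writeLines(paste(c(chrom, format(round(panel$positions[j]), scientific = FALSE),
                       panel$snp_ids[j], "A", "G", ".", "PASS", "AA=A", "GT",
                       gt[, j]), collapse = "\t"), con)
  invisible(path)
}

#' Read a phased VCF into a haplotype panel
#'
#' Uses `vcfR` to parse the file; sites without a phased biallelic genotype
#' or without an `AA` INFO tag consistent with REF/ALT are dropped. The
#' derived allele is the one differing from `AA`.
#'
#' @param path VCF file path.
#' @param rate_cM_Mb uniform recombination rate for the genetic map.
#' @return A [haplotype_panel].
#' @export
read_panel_vcf <- function(path, rate_cM_Mb = 1) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_panel_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  aa <- vcfR::extract.info(v, "AA")
  ref <- vcfR::getREF(v); alt <- vcfR::getALT(v)
  pos <- as.numeric(vcfR::getPOS(v))
  keep <- !is.na(aa) & (aa == ref | aa == alt) & !grepl(",", alt)
  gt <- gt[keep, , drop = FALSE]
  h1 <- substr(gt, 1, 1) == "1"; h2 <- substr(gt, 3, 3) == "1"
  H <- matrix(0L, 2 * ncol(gt), sum(keep))
  H[seq(1, nrow(H), 2), ] <- t(h1 * 1L)
  H[seq(2, nrow(H), 2), ] <- t(h2 * 1L)
  flip <- aa[keep] == alt[keep]   # derived allele is REF at these sites
  H[, flip] <- 1L - H[, flip]
  o <- order(pos[keep])
  haplotype_panel(H[, o, drop = FALSE], pos[keep][o],
                  rate_cM_Mb = rate_cM_Mb,
                  snp_ids = rownames(gt)[o])
}
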