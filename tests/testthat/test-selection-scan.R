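test_that("Reynolds FST behaves at its anchor points", {
  # fixed difference: hand evaluation gives a = 1, b = 0 -> FST = 1
  expect_equal(reynolds_fst(c(50, 50), c(0, 50)), 1)
  # identical counts in large equal samples: |FST| small, may be negative
  expect_lt(abs(reynolds_fst(c(300, 1000), c(300, 1000))), 0.01)
  # pooling a population with itself
  set.seed(1)
  cnt <- cbind(rbinom(50, 400, 0.4), 400)
  expect_lt(abs(reynolds_fst(cnt, cnt)), 0.01)
  expect_error(reynolds_fst(c(0, 0), c(5, 10)), "zero sample")
  expect_error(reynolds_fst(c(0, 80), c(0, 90)), "monomorphic")
  # hand-coded estimator formula on random counts
  set.seed(2)
  for (i in 1:20) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    p1 <- x1 / n1; p2 <- x2 / n2
    h1 <- p1 * (1 - p1) / (n1 - 1); h2 <- p2 * (1 - p2) / (n2 - 1)
    a <- (p1 - p2)^2 - h1 - h2
    expect_equal(reynolds_fst(c(x1, n1), c(x2, n2)),
                 a / (a + n1 * h1 + n2 * h2), tolerance = 1e-12)
  }
})

test_that("PBS combines branch lengths correctly", {
  set.seed(3)
  A <- cbind(rbinom(40, 100, 0.6), 100)
  B <- cbind(rbinom(40, 100, 0.4), 100)
  C <- cbind(rbinom(40, 100, 0.2), 100)
  r <- pbs(A, B, C)
  # arithmetic oracle from the returned pairwise FSTs
  Tf <- function(f) -log(1 - pmin(pmax(ifelse(is.na(f), 0, f), 0), 1))
  expect_equal(r$pbs,
               (Tf(r$fst[, 1]) + Tf(r$fst[, 2]) - Tf(r$fst[, 3])) / 2)
  # identity: PBS_A + PBS_B + PBS_C = (T_AB + T_AC + T_BC) / 2
  rA <- pbs(A, B, C)$pbs; rB <- pbs(B, A, C)$pbs; rC <- pbs(C, A, B)$pbs
  f_ab <- reynolds_fst(A, B, per_snp = TRUE)
  f_ac <- reynolds_fst(A, C, per_snp = TRUE)
  f_bc <- reynolds_fst(B, C, per_snp = TRUE)
  expect_equal(rA + rB + rC, (Tf(f_ab) + Tf(f_ac) + Tf(f_bc)) / 2,
               tolerance = 1e-12)
  # all FST = 0 -> PBS = 0; equal FSTs f -> -log(1-f)/2
  same <- cbind(rep(30, 5), 60)
  expect_equal(pbs(same, same, same)$pbs, rep(0, 5))
  expect_warning(p1 <- pbs(c(50, 50), c(0, 50), c(0, 50)), "Inf")
  expect_true(is.infinite(p1$pbs))
})

test_that("EHH matches brute-force pair counting on a toy panel", {
  H <- rbind(c(1, 1, 1, 1, 0),
             c(1, 0, 1, 1, 1),
             c(0, 1, 0, 0, 1),
             c(0, 0, 0, 1, 0))
  pan <- toy_panel(H)
  for (allele in c(0L, 1L)) {
    e <- ehh(pan, 3, allele)
    for (r in seq_len(nrow(e)))
      expect_equal(e$ehh[r], oracle_ehh(H, 3, allele, e$snp[r]),
                   info = paste("allele", allele, "snp", e$snp[r]))
  }
  # identical haplotypes: EHH is identically 1
  pan1 <- toy_panel(rbind(c(1, 0, 1), c(1, 0, 1), c(1, 0, 1), c(1, 0, 1)))
  expect_true(all(ehh(pan1, 2, 0)$ehh == 1))
  # EHH is 1 at the core and non-increasing outward
  set.seed(4)
  H2 <- matrix(rbinom(10 * 12, 1, 0.5), 10, 12)
  H2[, 6] <- rep(c(0, 1), each = 5)
  pan2 <- toy_panel(H2)
  for (al in 0:1) for (sd_ in c("left", "right")) {
    e <- ehh(pan2, 6, al, sd_)
    expect_equal(e$ehh[1], 1)
    expect_true(all(diff(e$ehh) <= 1e-12))
  }
  expect_error(ehh(toy_panel(rbind(c(1, 1), c(0, 1))), 1, 1), "fewer than 2")
})

test_that("iHS matches the brute-force integration oracle and its symmetries", {
  set.seed(5)
  H <- matrix(rbinom(8 * 14, 1, 0.5), 8, 14)
  H[, 7] <- rep(0:1, 4)
  pan <- toy_panel(H, positions = (1:14) * 500, rate_cM_Mb = 50)
  sc <- ihs(pan, maf = 0.05, cutoff = 0.05, max_bp = 1e6,
            standardize = FALSE)
  for (r in seq_len(nrow(sc))) {
    j <- sc$snp[r]
    o <- lapply(c("left", "right"), function(sd_)
      list(a = oracle_ihh_side(pan, j, 0L, sd_),
           d = oracle_ihh_side(pan, j, 1L, sd_)))
    ihh_a <- o[[1]]$a$ihh + o[[2]]$a$ihh
    ihh_d <- o[[1]]$d$ihh + o[[2]]$d$ihh
    expect_equal(sc$ihs_unstd[r], log(ihh_a / ihh_d), tolerance = 1e-10)
  }
  # label-swap antisymmetry at every reported SNP
  pan_sw <- toy_panel(1L - H, positions = (1:14) * 500, rate_cM_Mb = 50)
  sc_sw <- ihs(pan_sw, standardize = FALSE)
  common <- intersect(sc$snp, sc_sw$snp)
  expect_gt(length(common), 0)
  expect_equal(sc$ihs_unstd[match(common, sc$snp)],
               -sc_sw$ihs_unstd[match(common, sc_sw$snp)],
               tolerance = 1e-10)
  # panel symmetric under swapping labels at the core: iHS = 0
  Hs <- rbind(c(0, 1, 0, 0), c(1, 1, 1, 0),
              c(1, 0, 1, 1), c(0, 0, 0, 1))
  # columns: swapping 0/1 maps haplotype set onto itself around core 2
  pan_s <- toy_panel(Hs)
  sc_s <- ihs(pan_s, standardize = FALSE, cutoff = 0.4)
  if (!is.null(sc_s) && 2 %in% sc_s$snp)
    expect_equal(sc_s$ihs_unstd[sc_s$snp == 2], 0, tolerance = 1e-12)
  # standardized scores have mean ~0 within frequency bins
  set.seed(6)
  Hbig <- matrix(rbinom(40 * 200, 1, runif(200, 0.1, 0.9)), 40, 200,
                 byrow = TRUE)
  panb <- toy_panel(Hbig, positions = (1:200) * 200, rate_cM_Mb = 100)
  scb <- ihs(panb, bin_width = 0.25)
  expect_lt(abs(mean(scb$ihs)), 0.3)
})

test_that("windowed Tajima's D applies the filter and the textbook formula", {
  # 10 haplotypes, 5 derived singletons on distinct haplotypes
  H <- matrix(0L, 10, 5)
  for (j in 1:5) H[j, j] <- 1L
  pan <- toy_panel(H, positions = c(1000, 2000, 3000, 4000, 5000))
  d <- tajimas_d(pan, window = 10000, min_snps = 5)
  expect_equal(nrow(d), 1)
  pi <- 5 * (1 * 9) / choose(10, 2)
  expect_equal(d$D, oracle_tajima_d(5, pi, 10))
  expect_lt(d$D, 0)
  # a window with 4 SNPs is dropped
  d4 <- tajimas_d(toy_panel(H[, 1:4],
                            positions = c(1000, 2000, 3000, 4000)),
                  window = 10000)
  expect_equal(nrow(d4), 0)
  expect_error(tajimas_d(toy_panel(H[1:3, ])), "at least 4")
  # equilibrium coalescent null: mean D near 0
  set.seed(7)
  Ds <- replicate(400, {
    cnt <- oracle_coalescent_sfs(20, 10)
    if (length(cnt) < 5) return(NA_real_)
    H <- sfs_to_matrix(20, cnt)
    site_stats(H)$tajimas_d
  })
  expect_lt(abs(mean(Ds, na.rm = TRUE)), 0.2)
})

test_that("empirical P values use tail ranks with worst-rank ties", {
  expect_equal(empirical_p(c(5, 3, 3, 1), "upper"), c(0.25, 0.75, 0.75, 1))
  x <- rnorm(100)
  expect_equal(empirical_p(x, "upper")[which.max(x)], 0.01)
  expect_equal(empirical_p(x, "upper")[which.min(x)], 1)
  expect_equal(empirical_p(c(5, 3, 3, 1), "lower"), c(1, 0.75, 0.75, 0.25))
})

test_that("block enrichment reduces to exact rank-sum results", {
  # complete separation, exact test: P = 1 / choose(8, 3)
  r <- block_enrichment(c(10, 11, 12), c(1, 2, 3, 4, 5), exact = TRUE)
  expect_equal(r$p, 1 / choose(8, 3))
  # U statistic equals hand rank-sum arithmetic for groups of 3 and 5
  a <- c(7, 9, 4); b <- c(1, 3, 8, 2, 6)
  r2 <- block_enrichment(a, b, exact = TRUE)
  rk <- rank(c(a, b))
  U <- sum(rk[1:3]) - 3 * 4 / 2
  expect_equal(unname(r2$U), U)
  expect_error(block_enrichment(numeric(0), 1:3), "nonempty")
  # identical distributions: rejection near the nominal rate
  set.seed(8)
  rej <- replicate(400, {
    block_enrichment(rnorm(12), rnorm(20))$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})

test_that("haplotype blocks follow the confidence-interval rule", {
  set.seed(9)
  n <- 150
  hapA <- rbinom(n, 1, 0.5); hapA2 <- rbinom(n, 1, 0.5)
  hapB <- rbinom(n, 1, 0.5); hapB2 <- rbinom(n, 1, 0.5)
  # two 5-SNP clusters in perfect LD internally, recombined freely between
  G <- cbind(hapA + hapA2, hapA + hapA2, hapA + hapA2, hapA + hapA2,
             hapA + hapA2,
             hapB + hapB2, hapB + hapB2, hapB + hapB2, hapB + hapB2,
             hapB + hapB2)
  pos <- c(1:5 * 1000, 200000 + 1:5 * 1000)
  bl <- haplotype_blocks(G, pos, min_snps = 5)
  expect_equal(nrow(bl), 2)
  expect_equal(bl$n_snps, c(5L, 5L))
  # equilibrium SNPs: no blocks
  G0 <- matrix(rbinom(n * 6, 2, 0.5), n, 6)
  expect_equal(nrow(haplotype_blocks(G0, 1:6 * 1000, min_snps = 2)), 0)
  # distance cap: perfect LD 600 kb apart is not merged
  G2 <- cbind(hapA + hapA2, hapA + hapA2)
  expect_equal(nrow(haplotype_blocks(G2, c(1000, 601000), min_snps = 2)), 0)
  expect_equal(nrow(haplotype_blocks(G2[, 1, drop = FALSE], 1000)), 0)
})

test_that("per-block maxima carry the association flag", {
  blocks <- data.frame(start_bp = c(1000, 50000), end_bp = c(2000, 60000),
                       first_snp = c(1L, 6L), last_snp = c(5L, 10L),
                       n_snps = c(5L, 5L))
  pos <- c(1200, 1500, 1900, 51000, 55000, 59000)
  sc <- c(0.2, 1.4, 0.3, 0.9, 2.5, 0.1)
  bm <- block_max_scores(blocks, pos, sc, assoc_pos = 1500)
  expect_equal(bm$max_score, c(1.4, 2.5))
  expect_equal(bm$associated, c(TRUE, FALSE))
})
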