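test_that("scan recovers a noiseless additive effect exactly", {
  set.seed(1)
  g <- matrix(rbinom(200 * 5, 2, 0.4), 200, 5,
              dimnames = list(NULL, paste0("snp", 1:5)))
  ph <- data.frame(trait = 2 * g[, 3])
  sc <- gwas_scan(g, ph, "trait", covariates = character())
  expect_equal(sc$beta[3], 2, tolerance = 1e-10)
  expect_lt(sc$p[3], 1e-200)
})

test_that("scan betas and SEs agree with a QR reference solver", {
  set.seed(2)
  n <- 150
  g <- matrix(rbinom(n * 8, 2, 0.3), n, 8,
              dimnames = list(NULL, paste0("snp", 1:8)))
  ph <- data.frame(trait = rnorm(n), age = runif(n, 20, 70),
                   sex = rbinom(n, 1, 0.5))
  sc <- gwas_scan(g, ph, "trait", covariates = c("age", "sex"))
  for (j in 1:8) {
    if (sc$monomorphic[j]) next
    fit <- summary(lm(ph$trait ~ g[, j] + ph$age + ph$sex))
    expect_equal(sc$beta[j], unname(coef(fit)[2, 1]), tolerance = 1e-8)
    expect_equal(sc$se[j], unname(coef(fit)[2, 2]), tolerance = 1e-8)
    expect_equal(sc$p[j], unname(coef(fit)[2, 4]), tolerance = 1e-8)
  }
})

test_that("permuted traits give the nominal false positive rate", {
  coh <- quick_cohort(n = 500, m = 400, seed = 31)
  ph <- coh$phenotypes
  set.seed(99)
  ph$trait <- sample(ph$trait)
  sc <- gwas_scan(coh$genotypes, ph, "trait")
  frac <- mean(sc$p[!sc$monomorphic] < 0.05)
  m_eff <- sum(!sc$monomorphic)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / m_eff))
})

test_that("collinear designs are rejected with a named pair", {
  set.seed(3)
  g <- matrix(rbinom(100 * 3, 2, 0.5), 100, 3,
              dimnames = list(NULL, c("a", "b", "dup")))
  g[, "dup"] <- g[, "a"]
  ph <- data.frame(trait = rnorm(100))
  expect_error(gwas_scan(g, ph, "trait", covariates = character(),
                         condition_on = c("a", "dup"), snps = "b"),
               "collinear")
  # conditioning on a duplicate of the tested SNP
  expect_error(gwas_scan(g, ph, "trait", covariates = character(),
                         condition_on = "dup", snps = "a"),
               "collinear|duplicates")
})

test_that("conditioning removes proxy signals but leaves independent ones", {
  set.seed(5)
  n <- 900
  causal <- rbinom(n, 2, 0.5)
  proxy <- causal
  flip <- runif(n) < 0.06               # high-LD proxy
  proxy[flip] <- rbinom(sum(flip), 2, 0.5)
  indep <- rbinom(n, 2, 0.4)            # second, unlinked causal SNP
  noisecol <- rbinom(n, 2, 0.3)
  G <- cbind(causal = causal, proxy = proxy, indep = indep, other = noisecol)
  ph <- data.frame(trait = causal + 0.7 * indep + rnorm(n))
  prim <- gwas_scan(G, ph, "trait", covariates = character())
  expect_lt(prim$p[prim$snp == "proxy"], 5e-8)
  cond <- conditioned_scan(G, ph, "trait", condition_on = "causal",
                           covariates = character())
  expect_gt(cond$p[cond$snp == "proxy"], 5e-8)      # proxy abolished
  expect_lt(cond$p[cond$snp == "indep"], 5e-8)      # independent remains
  # conditioning on an irrelevant SNP barely moves the P values
  cond2 <- conditioned_scan(G, ph, "trait", condition_on = "other",
                            covariates = character(),
                            snps = c("causal", "indep"))
  for (s in c("causal", "indep")) {
    l1 <- -log10(prim$p[prim$snp == s]); l2 <- -log10(cond2$p[cond2$snp == s])
    expect_lt(abs(l1 - l2) / l1, 0.1)
  }
})

test_that("stepwise search returns one index SNP per independent signal", {
  set.seed(6)
  n <- 1200
  g1 <- rbinom(n, 2, 0.5); g2 <- rbinom(n, 2, 0.4)
  noise <- matrix(rbinom(n * 4, 2, 0.3), n, 4)
  G <- cbind(g1 = g1, g2 = g2, noise)
  colnames(G) <- c("g1", "g2", paste0("n", 1:4))
  ph2 <- data.frame(trait = 0.8 * g1 + 0.8 * g2 + rnorm(n))
  expect_setequal(stepwise_signals(G, ph2, "trait", colnames(G),
                                   covariates = character()), c("g1", "g2"))
  ph1 <- data.frame(trait = 0.9 * g1 + rnorm(n))
  expect_equal(stepwise_signals(G, ph1, "trait", colnames(G),
                                covariates = character()), "g1")
  ph0 <- data.frame(trait = rnorm(n))
  expect_length(stepwise_signals(G, ph0, "trait", colnames(G),
                                 covariates = character()), 0)
})

test_that("epistasis scan finds product terms and respects its threshold", {
  expect_equal(epistasis_scan(matrix(rbinom(40, 2, .5), 20, 2,
                                     dimnames = list(NULL, c("a", "b"))),
                              data.frame(trait = rnorm(20)), "trait",
                              c("a", "b"),
                              covariates = character())$threshold, 0.05)
  set.seed(7)
  n <- 800
  G <- matrix(rbinom(n * 5, 2, 0.5), n, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  ph <- data.frame(trait = 0.3 * G[, 1] + 0.3 * G[, 2] +
                     0.9 * G[, 1] * G[, 2] + rnorm(n))
  es <- epistasis_scan(G, ph, "trait", colnames(G),
                       covariates = character())
  top <- es$pairs[which.min(es$pairs$p_int), ]
  expect_setequal(c(top$snp1, top$snp2), c("s1", "s2"))
  # additive trait: interaction rejections near the nominal rate
  ph0 <- data.frame(trait = 0.4 * G[, 1] + 0.4 * G[, 2] + rnorm(n))
  set.seed(8)
  pvals <- replicate(60, {
    G2 <- matrix(rbinom(n * 2, 2, 0.5), n, 2,
                 dimnames = list(NULL, c("x", "y")))
    epistasis_scan(G2, ph0, "trait", c("x", "y"),
                   covariates = character())$pairs$p_int
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.08)
})

test_that("multivariate Wald test matches the univariate t in one dimension", {
  set.seed(9)
  n <- 1200
  g <- rbinom(n, 2, 0.4)
  ph <- data.frame(trait = 0.35 * g + rnorm(n))
  G <- matrix(g, dimnames = list(NULL, "snp1"))
  uni <- gwas_scan(G, ph, "trait", covariates = character())
  w <- multivariate_wald(g, ph["trait"])
  expect_lt(abs(w$p - uni$p), 1e-6)
  # when the phenotypes share an environmental component, conditioning on
  # the unassociated one sharpens the associated one: the joint test wins
  set.seed(10)
  wins <- replicate(40, {
    g <- rbinom(500, 2, 0.4)
    u <- rnorm(500)                      # shared environment
    y1 <- 0.25 * g + u + rnorm(500, 0, 0.4)
    y2 <- u + rnorm(500, 0, 0.4)
    P <- data.frame(y1 = y1, y2 = y2)
    wp <- multivariate_wald(g, P)$p
    up <- gwas_scan(matrix(g, dimnames = list(NULL, "s")),
                    data.frame(trait = y1), "trait",
                    covariates = character())$p
    wp <= up
  })
  expect_gte(mean(wins), 0.75)
  expect_error(multivariate_wald(rbinom(50, 2, .5),
                                 cbind(1:50, 2 * (1:50))), "rank deficient")
})

test_that("meta-analysis pools by inverse variance", {
  m <- meta_analyze(c(1, 3), c(1, 1))
  expect_equal(m$beta, 2)
  expect_equal(m$se, 1 / sqrt(2))
  # zero-weight limit
  m2 <- meta_analyze(c(1.7, 99), c(0.2, Inf))
  expect_equal(m2$beta, 1.7)
  expect_equal(m2$se, 0.2)
  # brute-force weighted mean on five strata
  b <- c(0.2, -0.1, 0.5, 0.3, 0); s <- c(0.1, 0.4, 0.2, 0.15, 0.3)
  m3 <- meta_analyze(b, s)
  w <- 1 / s^2
  expect_equal(m3$beta, sum(w * b) / sum(w))
  expect_equal(m3$se, sqrt(1 / sum(w)))
  # identical strata: common beta, SE shrunk by 1/sqrt(k)
  m4 <- meta_analyze(rep(0.4, 4), rep(0.12, 4))
  expect_equal(m4$beta, 0.4)
  expect_equal(m4$se, 0.12 / 2)
  expect_warning(meta_analyze(1, 1), "single stratum")
})

test_that("tail strength follows its closed form", {
  n <- 50
  expect_equal(tail_strength((1:n) / (n + 1))$TS, 0, tolerance = 1e-12)
  expect_equal(tail_strength(c(0.01, 0.2, 0.5, 0.9))$TS, 0.3729167,
               tolerance = 1e-6)
  expect_equal(signif(tail_strength(runif(10), n_star = 160858)$TS_sd, 2),
               0.0025)
  expect_error(tail_strength(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("genomic inflation is calibrated, scale-equivariant and exact at the null median", {
  set.seed(11)
  x <- rchisq(1e5, 1)
  lam <- genomic_inflation(x)
  expect_lt(abs(lam - 1), 0.02)
  expect_equal(genomic_inflation(2 * x), 2 * lam)
  expect_equal(genomic_inflation(qchisq(0.5, 1)), 1)
})

test_that("TS and lambda are jointly near-null on the same null scan", {
  coh <- quick_cohort(n = 500, m = 2500, seed = 61)
  ph <- coh$phenotypes
  set.seed(62)
  ph$trait <- sample(ph$trait)
  sc <- gwas_scan(coh$genotypes, ph, "trait")
  p <- sc$p[!sc$monomorphic]
  ts <- tail_strength(p)
  expect_lt(abs(ts$TS), 3 / sqrt(ts$n_star))
  lam <- genomic_inflation(qchisq(p, 1, lower.tail = FALSE))
  expect_gt(lam, 0.9); expect_lt(lam, 1.1)
})
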