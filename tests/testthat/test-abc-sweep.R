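test_that("sweep parameter and demography contracts hold", {
  expect_error(sweep_params(0.06, 10000), "prior support")
  expect_error(sweep_params(0.01, 1000), "prior support")
  expect_error(demography_spec(t_split1_ya = 40000, t_split2_ya = 45000),
               "predate")
  d <- demography_spec()
  expect_true(all(unlist(d$scaled[c("N_anc", "N_afr", "N_ooa")]) >= 2))
  expect_error(simulate_sweep(sweep_params(0.01, 42229, check = FALSE),
                              demography_spec(t_split2_ya = 30000)),
               "postdate")
})

test_that("simulations are seed-reproducible", {
  p <- sweep_params(0.02, 15000)
  a <- simulate_sweep(p, segment = 5e4, seed = 5)
  b <- simulate_sweep(p, segment = 5e4, seed = 5)
  expect_identical(a$panels$EAS$H, b$panels$EAS$H)
  expect_identical(a$panels$AFR$positions, b$panels$AFR$positions)
  expect_equal(a$daf_eas, b$daf_eas)
})

test_that("neutral injected alleles drift around their starting frequency", {
  set.seed(6)
  dafs <- replicate(300, simulate_sweep(sweep_params(0, 20000),
                                        segment = 2e4)$daf_eas)
  # martingale property of drift: mean stays near the 1% initial frequency
  expect_lt(abs(mean(dafs) - 0.01), 0.012)
})

test_that("stronger selection stochastically dominates weaker selection", {
  set.seed(7)
  hi <- replicate(60, simulate_sweep(sweep_params(0.04, 20000),
                                     segment = 2e4)$daf_eas)
  lo <- replicate(60, simulate_sweep(sweep_params(0.005, 20000),
                                     segment = 2e4)$daf_eas)
  expect_lt(wilcox.test(hi, lo, alternative = "greater")$p.value, 0.01)
})

test_that("summary statistics match brute-force oracles on a toy window", {
  H_eas <- rbind(c(1, 0, 1, 0), c(1, 0, 1, 0), c(0, 1, 1, 0),
                 c(0, 0, 1, 1), c(0, 0, 0, 1), c(1, 1, 0, 0))
  H_eur <- rbind(c(0, 0, 1, 0), c(1, 0, 0, 0), c(0, 1, 1, 0),
                 c(0, 0, 0, 1), c(0, 0, 1, 1), c(0, 0, 0, 0))
  H_afr <- rbind(c(0, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 0, 0),
                 c(1, 0, 0, 1), c(0, 0, 1, 0), c(0, 0, 0, 0))
  pos <- c(9000, 9500, 10000, 10800)
  sim <- list(panels = list(AFR = toy_panel(H_afr, pos),
                            EUR = toy_panel(H_eur, pos),
                            EAS = toy_panel(H_eas, pos)),
              selected_pos = 10000, selected_col = 3,
              daf_eas = mean(H_eas[, 3]))
  ss <- summarize_sweep(sim, window = 4000)
  n <- 6
  # pairwise differences by explicit double loop
  pi_o <- 0
  for (a in 1:(n - 1)) for (b in (a + 1):n)
    pi_o <- pi_o + sum(H_eas[a, ] != H_eas[b, ])
  pi_o <- pi_o / choose(n, 2)
  expect_equal(unname(ss["pi"]), pi_o, tolerance = 1e-10)
  expect_equal(unname(ss["tajimas_d"]), oracle_tajima_d(4, pi_o, 6),
               tolerance = 1e-10)
  # Fu & Li via independently coded constants
  a_n <- sum(1 / (1:5)); b_n <- sum(1 / (1:5)^2)
  c_n <- 2 * (6 * a_n - 10) / 20
  vD <- 1 + a_n^2 / (b_n + a_n^2) * (c_n - 7 / 5)
  uD <- a_n - 1 - vD
  eta_s <- sum(colSums(H_eas) == 1)
  expect_equal(unname(ss["fu_li_d"]),
               (4 - a_n * eta_s) / sqrt(uD * 4 + vD * 16), tolerance = 1e-10)
  vF <- (c_n + 2 * (36 + 6 + 3) / (9 * 6 * 5) - 2 / 5) / (a_n^2 + b_n)
  uF <- (1 + 7 / 15 - 4 * (7 / 25) * (a_n + 1 / 6 - 12 / 7)) / a_n - vF
  expect_equal(unname(ss["fu_li_f"]),
               (pi_o - eta_s) / sqrt(uF * 4 + vF * 16), tolerance = 1e-10)
  # Garud H from haplotype frequencies by hand
  key <- apply(H_eas, 1, paste, collapse = "")
  pfreq <- sort(table(key), decreasing = TRUE) / n
  h1 <- sum(pfreq^2)
  expect_equal(unname(ss["h1"]), unname(h1), tolerance = 1e-10)
  expect_equal(unname(ss["h2"]), unname(h1 - pfreq[1]^2), tolerance = 1e-10)
  expect_equal(unname(ss["h2_h1"]), unname((h1 - pfreq[1]^2) / h1),
               tolerance = 1e-10)
  # FSTs via the count route
  cnt <- function(H) cbind(colSums(H), nrow(H))
  expect_equal(unname(ss["fst_eas_eur"]),
               reynolds_fst(cnt(H_eas), cnt(H_eur)), tolerance = 1e-10)
  expect_equal(unname(ss["fst_eas_afr"]),
               reynolds_fst(cnt(H_eas), cnt(H_afr)), tolerance = 1e-10)
  expect_equal(unname(ss["daf"]), 4 / 6)
})

test_that("haplotype-homozygosity limits behave at sweeps", {
  mono <- matrix(1L, 8, 3)
  gh <- garud_h(mono)
  expect_equal(gh$h1, 1); expect_equal(gh$h2, 0); expect_equal(gh$h2_h1, 0)
  two <- rbind(matrix(0L, 4, 3), matrix(1L, 4, 3))
  gh2 <- garud_h(two)
  expect_equal(gh2$h1, 0.5); expect_equal(gh2$h2, 0.25)
  expect_equal(gh2$h2_h1, 0.5)
})

test_that("Box-Cox transform centers minima and finds the right power", {
  set.seed(8)
  X <- cbind(norm = rnorm(10000, 20, 3), lnorm = exp(rnorm(10000, 2, 0.4)))
  bc <- box_cox_transform(X)
  expect_equal(unname(1.5 - bc$shift), unname(apply(X, 2, min)))
  shifted_min <- apply(sweep(X, 2, bc$shift, "+"), 2, min)
  expect_true(all(shifted_min >= 1 & shifted_min <= 2))
  expect_lt(abs(bc$lambda["norm"] - 1), 0.2)
  expect_lt(abs(bc$lambda["lnorm"] - 0), 0.2)
  expect_warning(box_cox_transform(cbind(X, flat = rep(1, 10000))),
                 "constant")
  # reapplication reproduces the training transform
  tr <- apply_box_cox(bc, X[3, ])
  expect_equal(as.numeric(tr), as.numeric(bc$transformed[3, ]),
               tolerance = 1e-8)
})

test_that("PLS projection satisfies its contracts", {
  set.seed(9)
  Xr <- matrix(rnorm(600 * 6), 600, 6)
  X <- qr.Q(qr(scale(Xr, scale = FALSE)))[, 1:6] * sqrt(599)
  colnames(X) <- paste0("s", 1:6)   # centered, orthogonal, equal-variance
  w <- c(1, -2, 0.5, 0, 0, 1)
  Y <- cbind(par = as.vector(X %*% w))  # exact rank-1 linear link
  pp <- pls_project(X, Y, n_components = 1, fit_subset = 600)
  # fit-subset scores are standardized
  expect_lt(max(abs(colMeans(pp$scores[pp$fit_idx, , drop = FALSE]))), 1e-6)
  expect_lt(max(abs(apply(pp$scores[pp$fit_idx, , drop = FALSE], 2, sd) - 1)),
            1e-6)
  # one component captures a noiseless linear parameter exactly
  pred <- stats::predict(pp$model, X)$predict[, , 1]
  rmse <- sqrt(mean((pred - Y)^2))
  expect_lt(rmse / sd(Y), 1e-6)
  expect_error(pls_project(X[, c(1, 1, 2)], Y[, 1], n_components = 3),
               "rank")
  # permuted parameters carry no information: predicted error near 1
  set.seed(10)
  Yp <- Y[sample(nrow(Y)), , drop = FALSE]
  ppp <- pls_project(X, Yp, n_components = 2, fit_subset = 600)
  pe <- cross_validate(ppp$scores, Yp, n_holdouts = 60, tolerance = 0.05)
  expect_true(all(pe > 0.5 & pe < 1.6))
})

test_that("rejection keeps the closest draws and orders its percentiles", {
  set.seed(11)
  S <- matrix(rnorm(1000 * 3), 1000, 3)
  par <- data.frame(s = runif(1000, 0, 0.05),
                    t_sel_ya = runif(1000, 5000, 42229))
  r <- rejection_abc(S, S[417, ], par, tolerance = 1 / 1000)
  expect_equal(r$n_accepted, 1L)
  expect_equal(r$accepted$s, par$s[417])
  r2 <- rejection_abc(S, rnorm(3), par, tolerance = 0.005)
  expect_equal(r2$n_accepted, 5L)
  expect_true(all(r2$posterior$q025 <= r2$posterior$median))
  expect_true(all(r2$posterior$median <= r2$posterior$q975))
  expect_true(all(r2$posterior$median >= c(0, 5000)))
  expect_true(all(r2$posterior$median <= c(0.05, 42229)))
  expect_error(rejection_abc(S, rnorm(3), par, tolerance = 0), "tolerance")
  expect_error(rejection_abc(S[1:100, ], rnorm(3), par[1:100, ],
                             tolerance = 0.005), "1/tolerance")
  # count rule across (n, tolerance) combinations
  for (n in c(400, 1000)) for (tol in c(0.01, 0.025, 0.2)) {
    rr <- rejection_abc(S[1:n, ], rnorm(3), par[1:n, ], tol)
    expect_equal(rr$n_accepted, max(1, round(tol * n)))
  }
})

test_that("cross-validation separates informative from uninformative links", {
  set.seed(12)
  S <- matrix(rnorm(800), 800, 1)
  par <- data.frame(s = as.vector(S) * 0.01 + 0.025)  # deterministic link
  pe <- cross_validate(S, par, n_holdouts = 50, tolerance = 0.01)
  expect_lt(pe, 0.05)
  par0 <- data.frame(s = runif(800, 0, 0.05))         # independent
  pe0 <- cross_validate(S, par0, n_holdouts = 50, tolerance = 0.01)
  expect_gt(pe0, 0.5)
})
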