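#' Summary statistics of a simulated (or observed) sweep region
#'
#' Computes the sweep-inference summary vector in a window centered on the
#' selected site: nucleotide diversity (mean pairwise differences),
#' Tajima's D, Fu & Li's D and F, Garud's H1, H2 and H2/H1 (haplotype
#' diversity), Reynolds FST between East Asians and Europeans and between
#' East Asians and Africans, and the derived allele frequency of the
#' selected variant. Single-population statistics are computed on the East
#' Asian sample (the population in which selection acts).
#'
#' @param sim a `sweep_sim` from [simulate_sweep], or a named list of three
#'   [haplotype_panel]s (`AFR`, `EUR`, `EAS`) plus `selected_pos` /
#'   `selected_col` / `daf_eas` entries.
#' @param window window size in bp centered on the selected site (default
#'   2e5).
#' @return A named numeric vector with components `pi`, `tajimas_d`,
#'   `fu_li_d`, `fu_li_f`, `h1`, `h2`, `h2_h1`, `fst_eas_eur`,
#'   `fst_eas_afr`, `daf`. With no segregating East Asian site in the
#'   window the frequency-spectrum statistics are `NA` (callers resample).
#' @export
summarize_sweep <- function(sim, window = 2e5) {
  panels <- sim$panels
  center <- sim$selected_pos
  lo <- center - window / 2; hi <- center + window / 2
  eas <- panels$EAS
  in_win <- eas$positions >= lo & eas$positions <= hi
  Heas <- eas$H[, in_win, drop = FALSE]
  st <- tryCatch(site_stats(Heas), error = function(e) NULL)
  if (is.null(st) || st$S == 0) {
    pi <- 0; td <- NA_real_; fd <- NA_real_; ff <- NA_real_
  } else {
    pi <- st$pi; td <- st$tajimas_d; fd <- st$fu_li_d; ff <- st$fu_li_f
  }
  gh <- garud_h(Heas)
  cnt <- function(panel) {
    sel <- panel$positions >= lo & panel$positions <= hi
    cbind(colSums(panel$H[, sel, drop = FALSE]), nrow(panel$H))
  }
  fst_pair <- function(a, b) {
    f <- tryCatch(reynolds_fst(a, b), error = function(e) NA_real_)
    if (is.na(f)) 0 else f
  }
  c_eas <- cnt(panels$EAS); c_eur <- cnt(panels$EUR); c_afr <- cnt(panels$AFR)
  c(pi = pi, tajimas_d = td, fu_li_d = fd, fu_li_f = ff,
    h1 = gh$h1, h2 = gh$h2, h2_h1 = gh$h2_h1,
    fst_eas_eur = fst_pair(c_eas, c_eur),
    fst_eas_afr = fst_pair(c_eas, c_afr),
    daf = sim$daf_eas)
}

#' Build an ABC reference table
#'
#' Draws parameters from the uniform priors, simulates each replicate and
#' summarizes it. Replicates with undefined frequency-spectrum statistics
#' (no segregating window site) are redrawn.
#'
#' @param n_sims number of simulations.
#' @param demography a [demography_spec].
#' @param prior_s,prior_t uniform prior bounds for `s` and the onset time
#'   (years ago).
#' @param segment,window,n_sample,... forwarded to [simulate_sweep] /
#'   [summarize_sweep].
#' @param seed integer seed for the whole table.
#' @param progress print a dot every 500 replicates.
#' @return A data frame: `s`, `t_sel_ya`, then the 10 summary columns.
#' @export
abc_reference_table <- function(n_sims, demography = demography_spec(),
                                prior_s = c(0, 0.05),
                                prior_t = c(5000, 42229),
                                segment = 5e4, window = 2e4, n_sample = 50,
                                seed = 1L, progress = FALSE, ...) {
  set.seed(seed)
  out <- vector("list", n_sims)
  i <- 1L
  while (i <= n_sims) {
    par <- sweep_params(stats::runif(1, prior_s[1], prior_s[2]),
                        stats::runif(1, prior_t[1], prior_t[2]))
    sim <- simulate_sweep(par, demography, segment = segment,
                          n_sample = n_sample, ...)
    ss <- summarize_sweep(sim, window = window)
    if (anyNA(ss)) next  # undefined spectrum stats: redraw
    out[[i]] <- c(s = par$s, t_sel_ya = par$t_sel_ya, ss)
    if (progress && i %% 500 == 0) cat(".")
    i <- i + 1L
  }
  if (progress) cat("\n")
  as.data.frame(do.call(rbind, out))
}

#' Box-Cox transform a matrix of summary statistics
#'
#' Per statistic: shift so the minimum lies in `[1, 2]` (shift =
#' `1.5 - min`), then apply the Box-Cox power with the lambda maximizing
#' the profile normal likelihood over the simulation set. The per-statistic
#' shift and lambda are stored so the same transform can be applied to
#' observed statistics. Constant statistics are dropped with a warning.
#'
#' @param stats numeric matrix or data frame (simulations x statistics).
#' @param lambda_grid candidate lambdas (default `seq(-2, 2, 0.05)`).
#' @return A list of class `box_cox_transform`: `transformed` (matrix),
#'   `shift`, `lambda` (named vectors over kept columns), `kept`.
#' @export
box_cox_transform <- function(stats, lambda_grid = seq(-2, 2, 0.05)) {
  X <- as.matrix(stats)
  keep <- apply(X, 2, function(x) length(unique(x)) > 1)
  if (!all(keep))
    warning("dropping constant statistic(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  shift <- 1.5 - apply(X, 2, min)
  lambda <- numeric(ncol(X))
  TR <- X
  for (j in seq_len(ncol(X))) {
    x <- X[, j] + shift[j]
    bc <- MASS::boxcox(x ~ 1, lambda = lambda_grid, plotit = FALSE)
    lambda[j] <- bc$x[which.max(bc$y)]
    TR[, j] <- .bc_apply(x, lambda[j])
  }
  names(shift) <- names(lambda) <- colnames(X)
  structure(list(transformed = TR, shift = shift, lambda = lambda,
                 kept = colnames(X)),
            class = "box_cox_transform")
}

.bc_apply <- function(x, lambda) {
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

#' Apply a fitted Box-Cox transform to new statistics
#'
#' @param transform a `box_cox_transform`.
#' @param newstats named vector or matrix of raw statistics.
#' @return Transformed matrix over the transform's kept columns.
#' @export
apply_box_cox <- function(transform, newstats) {
  M <- if (is.matrix(newstats)) newstats else matrix(newstats, 1,
    dimnames = list(NULL, names(newstats)))
  M <- M[, transform$kept, drop = FALSE]
  for (j in seq_along(transform$kept)) {
    x <- pmax(M[, j] + transform$shift[j], 1e-8)
    M[, j] <- .bc_apply(x, transform$lambda[j])
  }
  M
}

#' Partial-least-squares reduction of summary statistics
#'
#' Fits a PLS regression of the parameters on the (transformed) statistics
#' using a subset of the simulations, then projects all simulations (and
#' later the observation) onto the first `n_components` components,
#' standardizing each component to unit variance on the fit subset. PLS
#' picks the linear combinations of statistics most informative about the
#' parameters, which is where Euclidean distance for rejection is taken.
#'
#' @param stats transformed statistic matrix (simulations x statistics).
#' @param params matrix/data frame of parameters (simulations x 2).
#' @param n_components number of PLS components (default 7; must not
#'   exceed the rank of the statistics).
#' @param fit_subset number of simulations used for fitting (default
#'   10000, capped at the table size).
#' @return A list of class `pls_projection`: `scores` (all simulations),
#'   `project(newstats)` closure, `n_components`, `fit_idx`.
#' @export
pls_project <- function(stats, params, n_components = 7,
                        fit_subset = 10000) {
  X <- as.matrix(stats); Y <- as.matrix(params)
  if (is.null(colnames(X))) colnames(X) <- paste0("stat", seq_len(ncol(X)))
  rk <- qr(scale(X, scale = FALSE))$rank
  if (n_components > rk)
    stop("n_components (", n_components, ") exceeds the statistic rank (",
         rk, ")")
  fit_idx <- seq_len(min(fit_subset, nrow(X)))
  fit <- mixOmics::pls(X[fit_idx, , drop = FALSE],
                       Y[fit_idx, , drop = FALSE],
                       ncomp = n_components, mode = "regression",
                       scale = TRUE)
  sc_fit <- fit$variates$X
  sds <- apply(sc_fit, 2, stats::sd)
  project <- function(newstats) {
    M <- if (is.matrix(newstats)) newstats else
      matrix(newstats, 1, dimnames = list(NULL, colnames(X)))
    colnames(M) <- colnames(X)
    v <- stats::predict(fit, M)$variates
    sweep(v, 2, sds, "/")
  }
  structure(list(scores = project(X), project = project,
                 n_components = n_components, fit_idx = fit_idx,
                 model = fit),
            class = "pls_projection")
}

#' Rejection ABC
#'
#' Keeps the `round(tolerance * n)` simulations closest (Euclidean
#' distance in the projected summary space) to the observation; ties are
#' broken by simulation index. The posterior is summarized by the median
#' and the 2.5/97.5 percentiles per parameter.
#'
#' @param sim_scores projected simulation summaries (n x k).
#' @param obs_score projected observed summary (length k or 1 x k).
#' @param params data frame/matrix of parameter draws (n rows).
#' @param tolerance acceptance rate in (0, 1] (default 0.005, i.e. the
#'   closest 0.5 percent).
#' @return A list of class `abc_result`: `accepted` (data frame of
#'   accepted draws), `posterior` (data frame with `median`, `q025`,
#'   `q975` per parameter), `tolerance`, `n_accepted`, `distances`.
#' @export
rejection_abc <- function(sim_scores, obs_score, params, tolerance = 0.005) {
  if (tolerance <= 0 || tolerance > 1) stop("tolerance must lie in (0, 1]")
  S <- as.matrix(sim_scores)
  o <- as.numeric(obs_score)
  n <- nrow(S)
  if (n < 1 / tolerance)
    stop("need at least 1/tolerance simulations")
  d <- sqrt(colSums((t(S) - o)^2))
  n_acc <- max(1L, round(tolerance * n))
  acc <- order(d)[seq_len(n_acc)]   # order() is stable: ties by index
  P <- as.data.frame(params)[acc, , drop = FALSE]
  post <- data.frame(
    parameter = names(P),
    median = vapply(P, stats::median, numeric(1)),
    q025 = vapply(P, stats::quantile, numeric(1), probs = 0.025),
    q975 = vapply(P, stats::quantile, numeric(1), probs = 0.975),
    row.names = NULL)
  structure(list(accepted = P, posterior = post, tolerance = tolerance,
                 n_accepted = n_acc, distances = d[acc]),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat("<abc_result> ", x$n_accepted, " accepted draws (tolerance ",
      x$tolerance, ")\n", sep = "")
  print(x$posterior, row.names = FALSE)
  invisible(x)
}

#' Leave-one-out validation of the ABC pipeline
#'
#' Treats each of `n_holdouts` simulations in turn as the observation, runs
#' rejection on the remaining table, and reports the predicted error per
#' parameter: mean squared error of the posterior median against the truth,
#' divided by the prior variance. Values near 1 mean the statistics carry
#' no information; near 0, full information.
#'
#' @param sim_scores projected simulation summaries.
#' @param params parameter draws (n rows).
#' @param n_holdouts number of held-out pseudo-observations (default 100).
#' @param tolerance rejection tolerance (default 0.005).
#' @param prior_var prior variances per parameter (default: empirical
#'   variance of the draws).
#' @return Named numeric vector of predicted errors.
#' @export
cross_validate <- function(sim_scores, params, n_holdouts = 100,
                           tolerance = 0.005, prior_var = NULL) {
  S <- as.matrix(sim_scores)
  P <- as.data.frame(params)
  n <- nrow(S)
  stopifnot(n_holdouts <= n)
  if (is.null(prior_var)) prior_var <- vapply(P, stats::var, numeric(1))
  hold <- seq_len(n_holdouts)
  err <- matrix(0, n_holdouts, ncol(P))
  for (i in hold) {
    r <- rejection_abc(S[-i, , drop = FALSE], S[i, ], P[-i, , drop = FALSE],
                       tolerance)
    err[i, ] <- (r$posterior$median - unlist(P[i, ]))^2
  }
  colMeans(err) / prior_var
}

#' Fit the sweep parameters by rejection ABC
#'
#' The full inference path: Box-Cox transform the reference table's
#' statistics, reduce them by PLS, project the observation, and keep the
#' closest fraction of simulations.
#'
#' @param obs_stats named vector of observed summary statistics (same
#'   components as [summarize_sweep]).
#' @param ref_table reference table from [abc_reference_table].
#' @param n_components PLS components (default 7).
#' @param tolerance rejection tolerance (default 0.005).
#' @param fit_subset simulations used to fit the PLS (default 10000).
#' @return An object of class `abc_sweep_fit`: the `abc_result` plus the
#'   fitted transform and projection.
#' @export
abc_sweep_fit <- function(obs_stats, ref_table, n_components = 7,
                          tolerance = 0.005, fit_subset = 10000) {
  stat_cols <- setdiff(names(ref_table), c("s", "t_sel_ya"))
  bc <- box_cox_transform(ref_table[stat_cols])
  pls <- pls_project(bc$transformed, ref_table[c("s", "t_sel_ya")],
                     n_components = min(n_components, length(bc$kept)),
                     fit_subset = fit_subset)
  obs_bc <- apply_box_cox(bc, obs_stats)
  obs_score <- pls$project(obs_bc)
  res <- rejection_abc(pls$scores, obs_score,
                       ref_table[c("s", "t_sel_ya")], tolerance)
  structure(c(res, list(box_cox = bc, pls = pls, obs_stats = obs_stats)),
            class = c("abc_sweep_fit", "abc_result"))
}

#' @export
summary.abc_sweep_fit <- function(object, ...) {
  cat("Rejection ABC sweep fit\n")
  cat("  simulations: ", length(object$pls$fit_idx), " (PLS fit) of ",
      nrow(object$pls$scores), "; components: ", object$pls$n_components,
      "; tolerance: ", object$tolerance, "\n", sep = "")
  cat("  posterior (median [95% CI]):\n")
  p <- object$posterior
  cat(sprintf("    s     : %.4f [%.4f, %.4f]\n", p$median[1], p$q025[1],
              p$q975[1]))
  cat(sprintf("    onset : %.0f ya [%.0f, %.0f]\n", p$median[2], p$q025[2],
              p$q975[2]))
  invisible(object)
}
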