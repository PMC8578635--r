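#' IC25 of a decatenation run with bootstrap confidence interval
#'
#' Fits a decreasing 4PL to percent decatenation (100 = full enzyme
#' activity) vs inhibitor dose and inverts at the 75%-remaining-activity
#' level, i.e. the dose inhibiting 25% of total decatenation. An optional
#' mask removes doses outside the compound's active range before fitting
#' (as required when a compound never reaches its IC50 within the tested
#' range). Estimates falling outside the tested dose range are flagged
#' `extrapolated` but still returned.
#'
#' @param doses inhibitor concentrations (µM).
#' @param percent percent decatenation relative to drug-free control.
#' @param level inhibition level as percent of total (default 25; use 50
#'   for relaxation-style IC50s).
#' @param mask optional: either a logical keep-vector over points or a
#'   numeric vector of doses to exclude.
#' @param n_boot bootstrap resamples for the CI (0 skips the CI).
#' @param seed bootstrap seed.
#' @return list of class `icx_estimate`: `icx`, `level`, `ci`, `fit`,
#'   `extrapolated`.
#' @export
run_ic25 <- function(doses, percent, level = 25, mask = NULL,
                     n_boot = 1000, seed = 1) {
  keep <- rep(TRUE, length(doses))
  if (!is.null(mask)) {
    keep <- if (is.logical(mask)) mask else !(doses %in% mask)
  }
  d <- doses[keep]; y <- percent[keep]
  if (length(unique(d[d > 0])) < 4) stop("insufficient design after masking")
  fit <- fit_4pl(d, y, direction = "decreasing")
  target <- 100 - level
  icx <- inverse_concentration(fit, target, scale = "absolute")
  ci <- NULL
  if (n_boot > 0) {
    ci <- bootstrap_ci(d, y,
                       statistic = function(f)
                         inverse_concentration(f, target, scale = "absolute"),
                       n_boot = n_boot, seed = seed,
                       direction = "decreasing")
  }
  structure(list(icx = icx, level = level, ci = ci, fit = fit,
                 extrapolated = icx < min(d) || icx > max(d)),
            class = "icx_estimate")
}

.split_runs <- function(decat) {
  stopifnot(all(c("run", "enzyme", "dose_uM", "percent_decatenation")
                %in% names(decat)))
  lapply(split(decat, decat$run), function(r) {
    enz <- sort(unique(r$enzyme))
    stopifnot(length(enz) == 2)
    a <- r[r$enzyme == enz[1], ]; b <- r[r$enzyme == enz[2], ]
    a <- a[order(a$dose_uM), ]; b <- b[order(b$dose_uM), ]
    stopifnot(all(a$dose_uM == b$dose_uM))
    list(doses = a$dose_uM, A = a$percent_decatenation,
         B = b$percent_decatenation, enzymes = enz)
  })
}

#' Aggregate paralog fold preference across replicate runs
#'
#' For each run, estimates the IC25 of each enzyme paralog (A and B,
#' e.g. TOP2A and TOP2B) and forms the per-run log ratio
#' `log(IC25_A / IC25_B)`. The aggregate fold preference is the geometric
#' mean `exp(mean log ratio)` — a value above 1 means less compound is
#' needed against paralog B — with a t-interval on the per-run log ratios
#' as 95% CI. Runs whose fit fails for either enzyme are dropped and
#' logged; fewer than 3 surviving runs is an error. A percent-difference
#' summary `100 (IC25_A - IC25_B) / IC25_A` is also reported per run.
#'
#' @param decat long-format data frame with columns `run`, `enzyme` (two
#'   levels; the first in sort order is "A"), `dose_uM`,
#'   `percent_decatenation`.
#' @param level inhibition level (default 25).
#' @param mask optional dose mask passed to [run_ic25()].
#' @return list of class `preference_estimate`: `fold_preference`, `ci`,
#'   per-run `ic25_A`, `ic25_B`, `log_ratio`, `percent_difference`,
#'   `dropped_runs`, `enzymes`.
#' @export
preference_ratio <- function(decat, level = 25, mask = NULL) {
  runs <- .split_runs(decat)
  lr <- icA <- icB <- rep(NA_real_, length(runs))
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    est <- tryCatch(list(
      A = run_ic25(r$doses, r$A, level = level, mask = mask, n_boot = 0),
      B = run_ic25(r$doses, r$B, level = level, mask = mask, n_boot = 0)),
      error = function(e) NULL)
    if (is.null(est)) next
    icA[i] <- est$A$icx; icB[i] <- est$B$icx
    lr[i] <- log(icA[i] / icB[i])
  }
  ok <- is.finite(lr)
  if (sum(ok) < 3) stop("insufficient runs: < 3 runs with both enzymes fit")
  m <- mean(lr[ok]); s <- stats::sd(lr[ok]); R <- sum(ok)
  half <- stats::qt(0.975, R - 1) * s / sqrt(R)
  structure(list(fold_preference = exp(m), ci = exp(c(m - half, m + half)),
                 ic25_A = icA, ic25_B = icB, log_ratio = lr,
                 percent_difference = 100 * (icA - icB) / icA,
                 dropped_runs = names(runs)[!ok],
                 enzymes = runs[[1]]$enzymes, n_runs = R, level = level),
            class = "preference_estimate")
}

#' @export
print.preference_estimate <- function(x, ...) {
  cat(sprintf("Paralog preference (%s / %s), IC%d fold ratio: %.3g (95%% CI %.3g-%.3g) over %d runs\n",
              x$enzymes[1], x$enzymes[2], x$level, x$fold_preference,
              x$ci[1], x$ci[2], x$n_runs))
  invisible(x)
}

#' Simulation-based two-sided test of paralog preference
#'
#' Tests H0: no difference between the paralogs' inhibition curves. Null
#' datasets are generated per run by fitting a single pooled 4PL to the
#' combined A+B data, randomly swapping the enzyme labels, and resampling
#' residuals (with replacement, pooled within run) around the shared
#' curve. The statistic is `|mean per-run log(IC25_A / IC25_B)|`; the
#' p-value is `(1 + #{null >= observed}) / (1 + n_sim)`, deterministic
#' given the seed.
#'
#' @inheritParams preference_ratio
#' @param n_sim number of null simulations (default 10,000; >= 100).
#' @param seed integer seed.
#' @return list of class `paralog_test`: `p_value`, `observed` (the
#'   statistic), `n_sim`, `seed`, `n_effective` (null sims with a valid
#'   statistic), and the `preference` estimate.
#' @export
simulation_test <- function(decat, n_sim = 10000, seed = 1, level = 25,
                            mask = NULL) {
  if (n_sim < 100) stop("too few simulations: n_sim must be >= 100")
  pref <- preference_ratio(decat, level = level, mask = mask)
  obs <- abs(mean(pref$log_ratio[is.finite(pref$log_ratio)]))
  runs <- .split_runs(decat)
  R <- length(runs)
  # shared masked design (runs share a design by construction)
  keep <- rep(TRUE, length(runs[[1]]$doses))
  if (!is.null(mask)) {
    keep <- if (is.logical(mask)) mask else !(runs[[1]]$doses %in% mask)
  }
  d <- runs[[1]]$doses[keep]
  x <- log(d)
  n <- length(d)
  q <- 100 - level

  pooled_par <- matrix(NA_real_, R, 4)
  resid_pool <- matrix(NA_real_, R, 2 * n)
  for (i in seq_len(R)) {
    r <- runs[[i]]
    dd <- c(d, d); yy <- c(r$A[keep], r$B[keep])
    pf <- fit_4pl(dd, yy, direction = "decreasing")
    pooled_par[i, ] <- c(pf$lower, pf$upper, log(pf$ec50), pf$hill)
    # df-correct the residuals: the pooled fit absorbs 4 parameters, so
    # raw residuals underestimate the noise scale (standard residual-
    # bootstrap inflation by sqrt(m / (m - p)))
    m <- length(yy)
    resid_pool[i, ] <- (yy - predict(pf, dd)) * sqrt(m / (m - 4))
  }
  pred <- t(vapply(seq_len(R), function(i)
    fourpl_value(d, pooled_par[i, 1], pooled_par[i, 2], pooled_par[i, 4],
                 exp(pooled_par[i, 3])), numeric(n)))

  set.seed(seed)
  total <- n_sim * R
  idxA <- matrix(sample.int(2 * n, total * n, replace = TRUE), nrow = total)
  idxB <- matrix(sample.int(2 * n, total * n, replace = TRUE), nrow = total)
  swap <- matrix(stats::runif(total) < 0.5, nrow = n_sim)  # label swap
  run_of_row <- rep(seq_len(R), times = n_sim)
  YA <- pred[run_of_row, , drop = FALSE] +
    matrix(resid_pool[cbind(rep(run_of_row, each = n), as.vector(t(idxA)))],
           nrow = total, byrow = TRUE)
  YB <- pred[run_of_row, , drop = FALSE] +
    matrix(resid_pool[cbind(rep(run_of_row, each = n), as.vector(t(idxB)))],
           nrow = total, byrow = TRUE)
  sw <- as.vector(t(swap))
  if (any(sw)) {
    tmp <- YA[sw, , drop = FALSE]
    YA[sw, ] <- YB[sw, , drop = FALSE]
    YB[sw, ] <- tmp
  }
  stats_null <- .cpp_paralog_null_stats(x, YA, YB, pooled_par,
                                        as.integer(n_sim), as.integer(R),
                                        q, 300L, 1e-9)
  ok <- is.finite(stats_null)
  p <- (1 + sum(stats_null[ok] >= obs)) / (1 + sum(ok))
  structure(list(p_value = p, observed = obs, n_sim = n_sim, seed = seed,
                 n_effective = sum(ok), preference = pref),
            class = "paralog_test")
}
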