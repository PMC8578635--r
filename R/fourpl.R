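#' Fit a four-parameter log-logistic dose-response curve
#'
#' Least-squares fit of the 4PL model
#' \deqn{y(d) = lower + (upper - lower) / (1 + (d / ec50)^{-hill})}
#' on log-dose, the standard sigmoid underlying IC50/ICx estimation for
#' viability and enzyme-activity assays. The sign of `hill` encodes the
#' direction: `hill > 0` means the response rises with dose, `hill < 0`
#' that it falls (e.g. percent viability or percent decatenation).
#'
#' Initialization uses the response extremes for the asymptotes, the dose
#' bracketing the half-range crossing for `ec50`, and a multi-start over
#' hill slopes in `{-2, -1, 1, 2}`; the start with the lowest residual sum
#' of squares wins, ties resolved toward the smallest `|hill|`. The
#' optimizer is a Levenberg-Marquardt routine with relative SSE tolerance
#' `1e-10` and at most 10,000 steps. When it fails to converge the
#' best-found parameters are still returned with `converged = FALSE`.
#'
#' Doses equal to zero are allowed in the input but excluded from the
#' log-dose fit (they carry no information about the slope in log space);
#' [predict()] handles them as the limiting asymptote.
#'
#' @param doses numeric vector of concentrations (>= 0, same unit for all).
#' @param responses numeric vector of responses (viability fraction,
#'   percent effect, percent activity, ...), same length as `doses`.
#' @param direction `"decreasing"` or `"increasing"`: expected response
#'   trend with dose. Used only to orient the starting values; both hill
#'   signs are tried regardless.
#' @param fixed_lower,fixed_upper optionally pin an asymptote to a known
#'   value (used e.g. by the ZIP conditional fits); `NULL` leaves it free.
#' @param maxit,tol optimizer controls.
#' @return An object of class `fourpl_fit` with elements `lower`, `upper`,
#'   `hill`, `ec50`, `sse`, `converged`, `n`, and the data used.
#'   Canonicalized so that `lower <= upper` (swapping asymptotes and
#'   negating `hill` leaves the curve unchanged).
#' @examples
#' d <- 0.3 * 2^(-5:6)
#' y <- 100 / (1 + (d / 0.3)^-1.5)
#' fit_4pl(d, y, direction = "increasing")
#' @export
fit_4pl <- function(doses, responses,
                    direction = c("decreasing", "increasing"),
                    fixed_lower = NULL, fixed_upper = NULL,
                    maxit = 10000, tol = 1e-10) {
  direction <- match.arg(direction)
  stopifnot(length(doses) == length(responses))
  keep <- is.finite(doses) & is.finite(responses) & doses > 0
  d <- doses[keep]
  y <- responses[keep]
  if (length(unique(d)) < 4) {
    stop("insufficient design: need >= 4 distinct nonzero doses")
  }
  if (diff(range(y)) <= .Machine$double.eps^0.5 * max(1, abs(mean(y)))) {
    stop("degenerate: no dose dependence")
  }
  x <- log(d)

  lo0 <- if (is.null(fixed_lower)) min(y) else fixed_lower
  up0 <- if (is.null(fixed_upper)) max(y) else fixed_upper
  free <- c(is.null(fixed_lower), is.null(fixed_upper), TRUE, TRUE)

  # ec50 start: dose bracketing the half-range crossing, in fitted order
  ord <- order(x)
  half <- (lo0 + up0) / 2
  ys <- y[ord]
  xs <- x[ord]
  cross <- which(diff(sign(ys - half)) != 0)
  m0 <- if (length(cross)) mean(xs[c(cross[1], cross[1] + 1)]) else stats::median(xs)

  hills <- if (direction == "increasing") c(1, 2, -1, -2) else c(-1, -2, 1, 2)
  starts <- do.call(rbind, lapply(hills, function(h) c(lo0, up0, m0, h)))

  res <- .cpp_fit4pl_best(x, y, starts, free, as.integer(maxit), tol)
  p <- res$par
  if (p[1] > p[2]) {  # canonical form: lower <= upper
    p <- c(p[2], p[1], p[3], -p[4])
  }
  structure(
    list(lower = p[1], upper = p[2], hill = p[4], ec50 = exp(p[3]),
         sse = res$sse, converged = isTRUE(res$converged),
         n = length(d), doses = d, responses = y, direction = direction),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("4PL log-logistic fit (", x$n, " points)\n", sep = "")
  cat(sprintf("  lower %.4g  upper %.4g  hill %.4g  ec50 %.4g\n",
              x$lower, x$upper, x$hill, x$ec50))
  cat(sprintf("  sse %.4g  converged %s\n", x$sse, x$converged))
  invisible(x)
}

#' Predicted response of a 4PL fit
#'
#' @param object a [fit_4pl()] result.
#' @param doses concentrations at which to evaluate the curve; dose 0
#'   returns the limiting asymptote.
#' @param ... unused.
#' @export
predict.fourpl_fit <- function(object, doses, ...) {
  fourpl_value(doses, object$lower, object$upper, object$hill, object$ec50)
}

#' Evaluate the 4PL curve at given parameters
#'
#' @param doses concentrations (>= 0).
#' @param lower,upper,hill,ec50 curve parameters.
#' @return predicted responses.
#' @export
fourpl_value <- function(doses, lower, upper, hill, ec50) {
  out <- numeric(length(doses))
  z <- doses > 0
  out[z] <- lower + (upper - lower) / (1 + (doses[z] / ec50)^(-hill))
  out[!z] <- if (hill > 0) lower else upper
  out
}

#' Invert a 4PL curve at an effect level (ICx)
#'
#' Closed-form inversion \eqn{d = ec50 \cdot (f / (1 - f))^{1 / hill}} with
#' \eqn{f = (effect - lower) / (upper - lower)}. The default `"absolute"`
#' scale interprets `effect_level` on the response scale itself (e.g. an
#' IC25 on a percent-of-total-activity assay is the dose at which the
#' response equals 75), matching "inhibit x% of total". The `"relative"`
#' scale interprets `effect_level` as a percent of the lower-to-upper span.
#'
#' @param fit a [fit_4pl()] result.
#' @param effect_level target response (absolute scale) or percent of span
#'   (relative scale).
#' @param scale `"absolute"` (default) or `"relative"`.
#' @return the concentration achieving the effect.
#' @export
inverse_concentration <- function(fit, effect_level,
                                  scale = c("absolute", "relative")) {
  scale <- match.arg(scale)
  f <- if (scale == "absolute") {
    (effect_level - fit$lower) / (fit$upper - fit$lower)
  } else {
    effect_level / 100
  }
  if (!is.finite(f) || f <= 0 || f >= 1) {
    stop("unreachable effect level: must lie strictly between the asymptotes")
  }
  fit$ec50 * (f / (1 - f))^(1 / fit$hill)
}

#' Case-resampling bootstrap confidence interval for a 4PL statistic
#'
#' Resamples data points (cases) with replacement, refits the curve, and
#' returns the percentile 2.5/97.5 interval of `statistic` over the
#' bootstrap refits. Deterministic for a given `seed`.
#'
#' @param doses,responses the data, as in [fit_4pl()].
#' @param statistic function of a `fourpl_fit` returning one number
#'   (e.g. `function(f) f$ec50`, or an ICx via [inverse_concentration()]).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @param ... passed on to [fit_4pl()] (direction, pinned asymptotes...).
#' @return numeric `c(lower, upper)` interval, with attributes `n_ok`
#'   (successful refits) and `estimate` (full-data statistic).
#' @export
bootstrap_ci <- function(doses, responses, statistic, n_boot = 1000,
                         seed = 1, level = 0.95, ...) {
  fit0 <- fit_4pl(doses, responses, ...)   # must succeed on the full data
  est <- statistic(fit0)
  keep <- is.finite(doses) & is.finite(responses) & doses > 0
  d <- doses[keep]; y <- responses[keep]
  n <- length(d)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  # guard against resamples with too few distinct doses
  X <- matrix(log(d)[t(idx)], nrow = n_boot, byrow = TRUE)
  Y <- matrix(y[t(idx)], nrow = n_boot, byrow = TRUE)
  warm <- matrix(rep(c(fit0$lower, fit0$upper, log(fit0$ec50), fit0$hill),
                     each = n_boot), nrow = n_boot)
  res <- .cpp_fit4pl_batch(X, Y, warm, rep(TRUE, 4), 2000L, 1e-10)
  vals <- vapply(seq_len(n_boot), function(i) {
    if (length(unique(X[i, ])) < 4) return(NA_real_)
    p <- res[i, 1:4]
    if (p[1] > p[2]) p <- c(p[2], p[1], p[3], -p[4])
    f <- structure(list(lower = p[1], upper = p[2], hill = p[4],
                        ec50 = exp(p[3]), sse = res[i, 5],
                        converged = res[i, 6] == 1),
                   class = "fourpl_fit")
    out <- tryCatch(statistic(f), error = function(e) NA_real_)
    if (is.finite(out)) out else NA_real_
  }, numeric(1))
  ok <- sum(is.finite(vals))
  if (ok < n_boot / 2) stop("unstable fit: >50% of bootstrap refits failed")
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(vals, c(a, 1 - a), na.rm = TRUE, type = 7))
  attr(ci, "n_ok") <- ok
  attr(ci, "estimate") <- est
  ci
}

#' IC50 from raw viability signal with vehicle normalization
#'
#' Normalizes raw plate-reader signal to the fraction of the mean vehicle
#' (e.g. DMSO) signal, fits a decreasing 4PL, and inverts at the 50%
#' absolute level (response fraction 0.5), as in a CellTiter-Glo rescreen.
#'
#' @param raw_signal raw signal at each dose.
#' @param vehicle_controls raw signals of vehicle-only control wells.
#' @param doses concentrations matching `raw_signal`.
#' @return list with the `fit` (on the fraction-of-vehicle scale) and
#'   `ic50`.
#' @export
ic50_from_viability <- function(raw_signal, vehicle_controls, doses) {
  v <- mean(vehicle_controls)
  if (!is.finite(v) || v <= 0) stop("invalid control: mean vehicle signal <= 0")
  frac <- raw_signal / v
  fit <- fit_4pl(doses, frac, direction = "decreasing")
  ic50 <- inverse_concentration(fit, 0.5, scale = "absolute")
  list(fit = fit, ic50 = ic50)
}
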