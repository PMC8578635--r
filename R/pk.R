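#' Trapezoidal area under the concentration-time curve
#'
#' Linear trapezoid rule over consecutive samples (a linear-up/log-down
#' variant is available via `method = "log_down"`, which uses the log
#' trapezoid on strictly declining positive segments).
#'
#' @param times sampling times (h), strictly increasing.
#' @param concentrations concentrations (µg/L), >= 0.
#' @param method `"linear"` (default) or `"log_down"`.
#' @return AUC from the first to the last sample (µg·h/L).
#' @export
auc_trapezoid <- function(times, concentrations, method = c("linear", "log_down")) {
  method <- match.arg(method)
  stopifnot(length(times) == length(concentrations))
  if (length(times) < 2) stop("insufficient samples: need >= 2")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  dt <- diff(times)
  c1 <- concentrations[-length(concentrations)]
  c2 <- concentrations[-1]
  seg <- (c1 + c2) / 2 * dt
  if (method == "log_down") {
    logseg <- c2 < c1 & c2 > 0 & c1 > 0
    seg[logseg] <- (c1[logseg] - c2[logseg]) /
      log(c1[logseg] / c2[logseg]) * dt[logseg]
  }
  sum(seg)
}

#' Terminal elimination rate and half-life
#'
#' Least-squares slope of ln(concentration) vs time over the final
#' `n_terminal` samples; `lambda_z = -slope`, `t_half = ln(2) / lambda_z`.
#'
#' @param times sampling times (h), strictly increasing.
#' @param concentrations concentrations (µg/L).
#' @param n_terminal number of terminal points to regress on (default 3).
#' @return list: `lambda_z` (1/h), `t_half` (h), `n_terminal_points`.
#' @export
terminal_half_life <- function(times, concentrations, n_terminal = 3) {
  stopifnot(length(times) == length(concentrations),
            length(times) >= n_terminal, n_terminal >= 2)
  idx <- seq(length(times) - n_terminal + 1, length(times))
  ct <- concentrations[idx]
  if (any(ct <= 0)) stop("log-undefined sample: zero concentration in terminal window")
  sl <- stats::coef(stats::lm(log(ct) ~ times[idx]))[2]
  if (sl >= 0) stop("no terminal decline")
  lambda_z <- -unname(sl)
  list(lambda_z = lambda_z, t_half = log(2) / lambda_z,
       n_terminal_points = n_terminal)
}

#' Average concentration over an interval against a target
#'
#' `c_avg = AUC / interval`; flags whether it meets a plasma exposure
#' target (boundary inclusive), e.g. maintaining Cavg above 100 µg/L.
#'
#' @param auc AUC over the interval (µg·h/L).
#' @param interval_h interval length (h), > 0.
#' @param threshold exposure target (µg/L, default 100).
#' @return list: `c_avg` (µg/L), `meets_target`.
#' @export
cavg_check <- function(auc, interval_h, threshold = 100) {
  stopifnot(interval_h > 0)
  c_avg <- auc / interval_h
  list(c_avg = c_avg, meets_target = c_avg >= threshold)
}

#' Non-compartmental PK summary for one concentration-time profile
#'
#' @param times,concentrations the profile (see [auc_trapezoid()]).
#' @param n_terminal terminal points for the half-life regression.
#' @param interval_h interval for Cavg (defaults to the profile span).
#' @param threshold Cavg target (µg/L).
#' @param method AUC rule, see [auc_trapezoid()].
#' @return list of class `nca_result`: `auc_0_t`, `lambda_z`, `t_half`,
#'   `c_avg`, `meets_target`, `n_terminal_points`.
#' @export
pk_nca <- function(times, concentrations, n_terminal = 3,
                   interval_h = NULL, threshold = 100,
                   method = c("linear", "log_down")) {
  auc <- auc_trapezoid(times, concentrations, method = method)
  hl <- terminal_half_life(times, concentrations, n_terminal = n_terminal)
  if (is.null(interval_h)) interval_h <- diff(range(times))
  ca <- cavg_check(auc, interval_h, threshold = threshold)
  structure(c(list(auc_0_t = auc), hl, ca, list(interval_h = interval_h)),
            class = "nca_result")
}
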