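#' Assemble a combination plate object
#'
#' A checkerboard combination experiment: two drugs at 12-point 1:2
#' dilution ladders, a full dose x dose grid of raw signal per replicate,
#' dedicated single-agent (monotherapy) wells, and shared vehicle (0% cell
#' death) and max-kill (100% cell death) control wells.
#'
#' @param drug1_id,drug2_id drug identifiers.
#' @param doses1,doses2 dose ladders in µM, strictly decreasing 1:2.
#' @param raw array `[n1, n2, n_rep]` of raw combination signal (rows index
#'   `doses1`, columns `doses2`).
#' @param mono1_raw,mono2_raw matrices `[n, n_rep]` of single-agent raw
#'   signal at the same ladders.
#' @param vehicle,maxkill vectors of control-well raw signals (>= 2 each).
#' @param cell_line_id cell line label.
#' @return object of class `combination_plate`.
#' @export
combination_plate <- function(drug1_id, drug2_id, doses1, doses2, raw,
                              mono1_raw, mono2_raw, vehicle, maxkill,
                              cell_line_id = NA_character_) {
  stopifnot(length(dim(raw)) == 3,
            dim(raw)[1] == length(doses1), dim(raw)[2] == length(doses2),
            nrow(mono1_raw) == length(doses1),
            nrow(mono2_raw) == length(doses2),
            length(vehicle) >= 2, length(maxkill) >= 2)
  r1 <- doses1[-length(doses1)] / doses1[-1]
  r2 <- doses2[-length(doses2)] / doses2[-1]
  if (any(doses1 <= 0) || any(doses2 <= 0) ||
      any(abs(r1 - 2) > 0.05) || any(abs(r2 - 2) > 0.05)) {
    stop("dose ladders must be strictly decreasing by factor 2")
  }
  structure(list(drug1_id = drug1_id, drug2_id = drug2_id,
                 doses1 = doses1, doses2 = doses2, raw = raw,
                 mono1_raw = mono1_raw, mono2_raw = mono2_raw,
                 vehicle = vehicle, maxkill = maxkill,
                 cell_line_id = cell_line_id),
            class = "combination_plate")
}

#' Normalize a combination plate to percent cell death
#'
#' Each well is normalized to the means of the inter-plate controls:
#' \deqn{\%death = 100 (\bar{v} - x) / (\bar{v} - \bar{k})}
#' with \eqn{\bar v} the mean vehicle (0% death) and \eqn{\bar k} the mean
#' max-kill (100% death) signal. Values are deliberately not clipped to
#' [0, 100]: replicate noise outside the bounds is kept honest for the
#' downstream t-tests.
#'
#' @param plate a [combination_plate()].
#' @return list of class `death_matrix`: `death` array `[n1, n2, n_rep]`,
#'   `mono1`, `mono2` matrices `[n, n_rep]`, plus doses and ids.
#' @export
normalize_plate <- function(plate) {
  v <- mean(plate$vehicle)
  k <- mean(plate$maxkill)
  if (!(v > k)) stop("invalid controls: vehicle mean must exceed max-kill mean")
  f <- function(x) 100 * (v - x) / (v - k)
  structure(list(death = f(plate$raw),
                 mono1 = f(plate$mono1_raw), mono2 = f(plate$mono2_raw),
                 doses1 = plate$doses1, doses2 = plate$doses2,
                 drug1_id = plate$drug1_id, drug2_id = plate$drug2_id,
                 cell_line_id = plate$cell_line_id),
            class = "death_matrix")
}

#' Zero-interaction-potency expectation
#'
#' The non-interaction expectation of the ZIP framework for two effects on
#' a percent scale: `E = y1 + y2 - y1 * y2 / 100`. Inputs are clamped to
#' [0, 100] inside the formula only (stored matrices are never clipped).
#'
#' @param y1,y2 percent cell death (any real; clamped copies are used).
#' @return expected percent death under independence.
#' @export
zip_expectation <- function(y1, y2) {
  a <- pmin(pmax(y1, 0), 100)
  b <- pmin(pmax(y2, 0), 100)
  a + b - a * b / 100
}

.fit_mono <- function(doses, y) {
  fit_4pl(doses, y, direction = "increasing")
}

#' ZIP delta synergy surface
#'
#' Computes the delta-ZIP surface of a combination grid: (i) 4PL fits to
#' each drug's monotherapy; (ii) for each grid column (drug 2 dose fixed) a
#' conditional 4PL in the drug 1 dose with the lower asymptote pinned to
#' the fitted drug 2 monotherapy effect at that dose, and symmetrically for
#' rows; (iii) the fitted combination response at each (c1, c2) is the mean
#' of the row-wise and column-wise conditional predictions; (iv)
#' \eqn{\delta(c1, c2)} is the fitted combination response minus the ZIP
#' expectation of the two monotherapy-fit predictions. Rows/columns whose
#' conditional fit fails fall back to the observed values and are flagged.
#'
#' @param death a `death_matrix` (see [normalize_plate()]), or a list with
#'   `death` (2-D matrix or 3-D replicate array, averaged over replicates
#'   here), `mono1`, `mono2`, `doses1`, `doses2`.
#' @param mode `"zip"` (conditional-fit scheme above, the reference
#'   behavior) or `"naive"` (observed minus expectation, no conditional
#'   fits).
#' @return object of class `synergy_surface`: `delta` matrix, `delta_max`,
#'   `delta_min`, `argmax_pair`, `argmin_pair` (dose pairs),
#'   `argmax_index`, `argmin_index`, monotherapy fits, fitted surface, and
#'   `fallback_rows`/`fallback_cols` flags.
#' @export
zip_delta_surface <- function(death, mode = c("zip", "naive")) {
  mode <- match.arg(mode)
  d1 <- death$doses1; d2 <- death$doses2
  grid <- death$death
  if (length(dim(grid)) == 3) grid <- apply(grid, c(1, 2), mean)
  m1 <- death$mono1; m2 <- death$mono2
  if (is.matrix(m1)) m1 <- rowMeans(m1)
  if (is.matrix(m2)) m2 <- rowMeans(m2)

  f1 <- tryCatch(.fit_mono(d1, m1), error = function(e) NULL)
  f2 <- tryCatch(.fit_mono(d2, m2), error = function(e) NULL)
  if (is.null(f1) && is.null(f2)) stop("no monotherapy signal")
  y1hat <- if (!is.null(f1)) predict(f1, d1) else m1
  y2hat <- if (!is.null(f2)) predict(f2, d2) else m2

  n1 <- length(d1); n2 <- length(d2)
  E <- outer(y1hat, y2hat, zip_expectation)

  if (mode == "naive") {
    fitted <- grid
    fb_rows <- rep(FALSE, n1); fb_cols <- rep(FALSE, n2)
  } else {
    pred_col <- matrix(NA_real_, n1, n2)  # conditional in drug1, per drug2 dose
    fb_cols <- logical(n2)
    for (j in seq_len(n2)) {
      fj <- tryCatch(
        fit_4pl(d1, grid[, j], direction = "increasing",
                fixed_lower = y2hat[j]),
        error = function(e) NULL)
      if (is.null(fj)) { pred_col[, j] <- grid[, j]; fb_cols[j] <- TRUE }
      else pred_col[, j] <- predict(fj, d1)
    }
    pred_row <- matrix(NA_real_, n1, n2)  # conditional in drug2, per drug1 dose
    fb_rows <- logical(n1)
    for (i in seq_len(n1)) {
      fi <- tryCatch(
        fit_4pl(d2, grid[i, ], direction = "increasing",
                fixed_lower = y1hat[i]),
        error = function(e) NULL)
      if (is.null(fi)) { pred_row[i, ] <- grid[i, ]; fb_rows[i] <- TRUE }
      else pred_row[i, ] <- predict(fi, d2)
    }
    fitted <- (pred_col + pred_row) / 2
  }

  delta <- fitted - E
  imax <- which(delta == max(delta), arr.ind = TRUE)[1, ]
  imin <- which(delta == min(delta), arr.ind = TRUE)[1, ]
  structure(list(delta = delta, fitted = fitted, expectation = E,
                 delta_max = max(delta), delta_min = min(delta),
                 argmax_pair = c(dose1 = d1[imax[1]], dose2 = d2[imax[2]]),
                 argmin_pair = c(dose1 = d1[imin[1]], dose2 = d2[imin[2]]),
                 argmax_index = unname(imax), argmin_index = unname(imin),
                 mono_fit1 = f1, mono_fit2 = f2,
                 y1hat = y1hat, y2hat = y2hat,
                 fallback_rows = fb_rows, fallback_cols = fb_cols,
                 doses1 = d1, doses2 = d2, mode = mode),
            class = "synergy_surface")
}

#' Call synergy/antagonism at the surface extrema
#'
#' At the highest- and lowest-scoring concentration pairs of the delta
#' surface, compares the per-replicate observed percent death with the ZIP
#' expectation from the monotherapy fits: per-replicate
#' `log2(observed / E)`, a one-sample two-sided t-test of those log2 fold
#' changes against 0, and classification by thresholds (defaults
#' `|log2 FC| >= 1.5` and `p <= 0.01`). Pairs at which the expectation is
#' non-positive, or at which a replicate's observed death is non-positive
#' (log2 undefined), are skipped in favor of the next-ranked pair and
#' logged.
#'
#' @param death a `death_matrix` with a replicate array (>= 2 replicates).
#' @param surface a [zip_delta_surface()] result on the same plate.
#' @param fc_threshold synergy threshold on the |log2 fold change|
#'   (default 1.5).
#' @param p_threshold p-value threshold (default 0.01).
#' @param fc_scale `"log2"` (default; threshold applies to |log2 FC|) or
#'   `"linear"` (threshold applies to the fold change itself).
#' @return object of class `combination_call` with `log2_fc_at_max`,
#'   `log2_fc_at_min`, `p_max`, `p_min`, `classification`
#'   (`synergy`/`antagonism`/`none`), the pairs used, and skipped pairs.
#' @export
call_combination <- function(death, surface, fc_threshold = 1.5,
                             p_threshold = 0.01,
                             fc_scale = c("log2", "linear")) {
  fc_scale <- match.arg(fc_scale)
  arr <- death$death
  stopifnot(length(dim(arr)) == 3, dim(arr)[3] >= 2)
  E <- outer(surface$y1hat, surface$y2hat, zip_expectation)

  eval_at <- function(ord) {
    skipped <- list()
    for (k in seq_along(ord)) {
      ij <- arrayInd(ord[k], dim(surface$delta))
      e <- E[ij[1], ij[2]]
      obs <- arr[ij[1], ij[2], ]
      if (!(e > 0)) {
        skipped[[length(skipped) + 1]] <-
          c(i = ij[1], j = ij[2], reason = "non-positive expectation")
        next
      }
      if (any(obs <= 0)) {
        skipped[[length(skipped) + 1]] <-
          c(i = ij[1], j = ij[2], reason = "non-positive observed death")
        next
      }
      lfc <- log2(obs / e)
      p <- if (stats::sd(lfc) == 0) {
        if (mean(lfc) == 0) 1 else 0
      } else {
        stats::t.test(lfc, mu = 0)$p.value
      }
      return(list(index = ij, log2_fc = mean(lfc), per_rep = lfc, p = p,
                  expectation = e, skipped = skipped))
    }
    list(index = NULL, log2_fc = NA_real_, per_rep = NULL, p = NA_real_,
         expectation = NA_real_, skipped = skipped)
  }

  at_max <- eval_at(order(surface$delta, decreasing = TRUE))
  at_min <- eval_at(order(surface$delta, decreasing = FALSE))

  exceeds <- function(lfc, sign) {
    if (!is.finite(lfc)) return(FALSE)
    if (fc_scale == "log2") sign * lfc >= fc_threshold
    else 2^(sign * lfc) >= fc_threshold
  }
  syn <- exceeds(at_max$log2_fc, 1) &&
    is.finite(at_max$p) && at_max$p <= p_threshold
  ant <- exceeds(at_min$log2_fc, -1) &&
    is.finite(at_min$p) && at_min$p <= p_threshold
  classification <- if (syn) "synergy" else if (ant) "antagonism" else "none"

  structure(list(log2_fc_at_max = at_max$log2_fc, p_max = at_max$p,
                 log2_fc_at_min = at_min$log2_fc, p_min = at_min$p,
                 classification = classification,
                 max_pair_index = at_max$index, min_pair_index = at_min$index,
                 per_rep_log2_fc_max = at_max$per_rep,
                 per_rep_log2_fc_min = at_min$per_rep,
                 skipped_pairs = c(at_max$skipped, at_min$skipped),
                 fc_threshold = fc_threshold, p_threshold = p_threshold),
            class = "combination_call")
}
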