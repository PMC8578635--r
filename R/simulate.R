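#' Simulate a lineage-annotated drug screening table
#'
#' Generates a long-format cell line x drug IC50 table with the structure
#' of a large pharmacogenomic screen. The log10 IC50 of line l on drug d
#' is `base_d + shift_d * [lineage = target] + e_tp53 * tp53_l +
#' e_mycn * mycn_l + noise`. Defaults anchor to the composition and effect
#' sizes of the screens the package targets: a target-lineage fraction of
#' 31/1001, drug-level baselines N(0.5, 0.6), a TP53-mutation effect of
#' +log10(17.45) and a MYCN-amplification effect of -log10(10.9) on log10
#' IC50 (genotype flags are drawn only within the target lineage, emulating
#' a neuroblastoma panel).
#'
#' @param n_lines,n_drugs table dimensions.
#' @param target_fraction expected fraction of target-lineage lines
#'   (default 31/1001); at least one target line is guaranteed.
#' @param target_lineage,other_lineage lineage labels.
#' @param base_mu,base_sigma per-drug baseline log10 IC50 distribution.
#' @param selective_shift named numeric vector of per-drug target-lineage
#'   shifts on log10 IC50 (negative = selective), or a single value
#'   recycled; drugs not named get 0.
#' @param tp53_effect,mycn_effect genotype effects on log10 IC50.
#' @param tp53_frac,mycn_frac genotype prevalence within the target
#'   lineage.
#' @param noise_sd residual sd on log10 IC50 (default 0.4).
#' @param missingness probability a (line, drug) record is dropped.
#' @param seed integer seed; identical seeds give identical output.
#' @return list: `screen` (data frame `cell_line`, `drug`, `ic50`),
#'   `annotations` (data frame `cell_line`, `lineage`, `mycn_amplified`,
#'   `tp53_mutant`), `truth` (all planted parameters).
#' @export
simulate_screen <- function(n_lines = 50, n_drugs = 50,
                            target_fraction = 31 / 1001,
                            target_lineage = "neuroblastoma",
                            other_lineage = "other",
                            base_mu = 0.5, base_sigma = 0.6,
                            selective_shift = 0,
                            tp53_effect = log10(17.45),
                            mycn_effect = -log10(10.9),
                            tp53_frac = 0.25, mycn_frac = 0.4,
                            noise_sd = 0.4, missingness = 0, seed = 1) {
  set.seed(seed)
  lines <- sprintf("CL%03d", seq_len(n_lines))
  drugs <- sprintf("drug%03d", seq_len(n_drugs))
  repeat {
    is_target <- stats::runif(n_lines) < target_fraction
    if (any(is_target)) break
    warning("no target-lineage line sampled; resampling")
  }
  mycn <- is_target & stats::runif(n_lines) < mycn_frac
  tp53 <- is_target & stats::runif(n_lines) < tp53_frac
  shifts <- stats::setNames(rep(0, n_drugs), drugs)
  if (!is.null(names(selective_shift))) {
    shifts[names(selective_shift)] <- selective_shift
  } else {
    shifts[] <- selective_shift
  }
  base <- stats::rnorm(n_drugs, base_mu, base_sigma)
  grid <- expand.grid(line = seq_len(n_lines), drug = seq_len(n_drugs))
  lg <- base[grid$drug] + shifts[grid$drug] * is_target[grid$line] +
    tp53_effect * tp53[grid$line] + mycn_effect * mycn[grid$line] +
    stats::rnorm(nrow(grid), 0, noise_sd)
  screen <- data.frame(cell_line = lines[grid$line], drug = drugs[grid$drug],
                       ic50 = 10^lg)
  if (missingness > 0) {
    screen <- screen[stats::runif(nrow(screen)) >= missingness, , drop = FALSE]
    rownames(screen) <- NULL
  }
  ann <- data.frame(cell_line = lines,
                    lineage = ifelse(is_target, target_lineage, other_lineage),
                    mycn_amplified = mycn, tp53_mutant = tp53)
  list(screen = screen, annotations = ann,
       truth = list(base = stats::setNames(base, drugs), shifts = shifts,
                    tp53_effect = tp53_effect, mycn_effect = mycn_effect,
                    noise_sd = noise_sd, seed = seed))
}

#' Simulate a checkerboard combination plate
#'
#' Builds a 12 x 12 combination plate whose true percent death is the ZIP
#' expectation of two 4PL monotherapy truths plus an interaction term
#' `delta_spec`, maps it back to raw signal through the inverse of the
#' control normalization, and adds Gaussian noise on the percent-death
#' scale. Default top concentrations follow a realistic combination
#' screen (1.89 µM and 19.93 µM) with 1:2 ladders over 12 points and 4
#' replicates.
#'
#' @param mono1,mono2 lists with elements `upper`, `hill`, `ec50` (lower
#'   asymptote 0) defining the monotherapy truths on the percent-death
#'   scale.
#' @param top1,top2 top concentrations of the 12-point 1:2 ladders (µM).
#' @param n_doses ladder length (default 12).
#' @param delta_spec interaction truth: `list(type = "zero")`,
#'   `list(type = "block", rows =, cols =, eps =)` (additive boost on a
#'   dose sub-block), or `list(type = "bump", center = c(i, j), width =,
#'   eps =)` (smooth Gaussian bump in grid index space).
#' @param noise_sd well noise, in percent-death points (default 2).
#' @param replicates number of replicate grids (default 4).
#' @param vehicle_mean,maxkill_mean,control_sd raw-signal control model.
#' @param n_controls control wells of each kind.
#' @param seed integer seed.
#' @return list: `plate` (a [combination_plate()]), `truth` (monotherapy
#'   truths, true delta matrix, config).
#' @export
simulate_combination_plate <- function(
    mono1 = list(upper = 95, hill = 1.3, ec50 = 0.12),
    mono2 = list(upper = 90, hill = 1.1, ec50 = 1.5),
    top1 = 1.89, top2 = 19.93, n_doses = 12,
    delta_spec = list(type = "zero"),
    noise_sd = 2, replicates = 4,
    vehicle_mean = 1e5, maxkill_mean = 2e3, control_sd = 0.01,
    n_controls = 8, seed = 1) {
  set.seed(seed)
  d1 <- top1 / 2^(0:(n_doses - 1))
  d2 <- top2 / 2^(0:(n_doses - 1))
  y1 <- fourpl_value(d1, 0, mono1$upper, mono1$hill, mono1$ec50)
  y2 <- fourpl_value(d2, 0, mono2$upper, mono2$hill, mono2$ec50)
  delta <- matrix(0, n_doses, n_doses)
  if (delta_spec$type == "block") {
    delta[delta_spec$rows, delta_spec$cols] <- delta_spec$eps
  } else if (delta_spec$type == "bump") {
    for (i in seq_len(n_doses)) for (j in seq_len(n_doses)) {
      delta[i, j] <- delta_spec$eps *
        exp(-((i - delta_spec$center[1])^2 + (j - delta_spec$center[2])^2) /
              (2 * delta_spec$width^2))
    }
  } else if (delta_spec$type != "zero") {
    stop("unknown delta_spec type")
  }
  truth_death <- outer(y1, y2, zip_expectation) + delta

  span <- vehicle_mean - maxkill_mean
  to_raw <- function(pct) vehicle_mean - pct / 100 * span
  raw <- array(NA_real_, c(n_doses, n_doses, replicates))
  for (r in seq_len(replicates)) {
    raw[, , r] <- to_raw(truth_death +
                           matrix(stats::rnorm(n_doses^2, 0, noise_sd),
                                  n_doses, n_doses))
  }
  mono1_raw <- matrix(to_raw(rep(y1, replicates) +
                               stats::rnorm(n_doses * replicates, 0, noise_sd)),
                      n_doses, replicates)
  mono2_raw <- matrix(to_raw(rep(y2, replicates) +
                               stats::rnorm(n_doses * replicates, 0, noise_sd)),
                      n_doses, replicates)
  vehicle <- stats::rnorm(n_controls, vehicle_mean, control_sd * vehicle_mean)
  maxkill <- stats::rnorm(n_controls, maxkill_mean, control_sd * vehicle_mean)
  plate <- combination_plate("drugA", "drugB", d1, d2, raw,
                             mono1_raw, mono2_raw, vehicle, maxkill,
                             cell_line_id = "SIM")
  list(plate = plate,
       truth = list(mono1 = mono1, mono2 = mono2, y1 = y1, y2 = y2,
                    delta = delta, death = truth_death,
                    noise_sd = noise_sd, seed = seed))
}

#' Simulate an expression/mediation/feature-selection cohort
#'
#' Generates the exposure -> mediator -> outcome chain underlying the
#' mediation analysis (`mediator = a * exposure + noise`,
#' `outcome = b * mediator + c * exposure + noise`) together with an
#' expression table (exposure and mediator genes plus housekeeping genes
#' at fixed TPM levels) and a feature matrix with three planted predictors
#' of the mediator among correlated noise features (38 columns total by
#' default), emulating a tumor-cohort feature-selection problem.
#'
#' @param n_samples cohort size (29 emulates the cell line mediation
#'   analysis, 88 the tumor feature model).
#' @param a exposure -> mediator path coefficient.
#' @param b mediator -> outcome path coefficient.
#' @param c_direct direct exposure -> outcome path (0 = full mediation).
#' @param sd_mediator,sd_outcome residual sds of the two structural
#'   equations.
#' @param n_features total feature columns (default 38).
#' @param n_planted number of features with a real effect on the mediator
#'   expression used as the ElasticNet response (default 3).
#' @param beta_planted standardized effect size of each planted feature
#'   (default 0.5).
#' @param feature_rho equicorrelation among the noise features.
#' @param sd_feature_noise residual sd of the feature-based mediator
#'   expression response.
#' @param housekeeping_tpm named TPM levels for housekeeping genes.
#' @param seed integer seed.
#' @return list: `expression` (genes x samples TPM matrix incl. EXPOSURE,
#'   MEDIATOR, housekeeping genes), `sensitivity` (outcome vector),
#'   `exposure`, `mediator` (latent log2-scale values), `features`
#'   (samples x n_features matrix), `enet_response` (mediator expression
#'   driven by the planted features), `truth`.
#' @export
simulate_expression_chain <- function(n_samples = 29, a = 0.8, b = 1,
                                      c_direct = 0, sd_mediator = 0.6,
                                      sd_outcome = 0.5, n_features = 38,
                                      n_planted = 3, beta_planted = 0.5,
                                      feature_rho = 0.3,
                                      sd_feature_noise = 0.5,
                                      housekeeping_tpm = c(ACTB = 1500,
                                                           GAPDH = 2000),
                                      seed = 1) {
  set.seed(seed)
  n <- n_samples
  exposure <- stats::rnorm(n)
  mediator <- a * exposure + stats::rnorm(n, 0, sd_mediator)
  outcome <- b * mediator + c_direct * exposure + stats::rnorm(n, 0, sd_outcome)

  # expression table on the TPM scale: latent values become log2(TPM + 1)
  base_expo <- 6; base_med <- 7
  tpm_expo <- pmax(2^(base_expo + exposure) - 1, 0)
  tpm_med <- pmax(2^(base_med + mediator) - 1, 0)
  hk <- t(vapply(housekeeping_tpm, function(v)
    pmax(v * 2^stats::rnorm(n, 0, 0.05), 0), numeric(n)))
  expr <- rbind(EXPOSURE = tpm_expo, MEDIATOR = tpm_med, hk)

  # feature matrix: equicorrelated noise + planted predictors
  z <- stats::rnorm(n)
  F <- sqrt(feature_rho) * matrix(z, n, n_features) +
    sqrt(1 - feature_rho) * matrix(stats::rnorm(n * n_features), n, n_features)
  colnames(F) <- sprintf("feat%02d", seq_len(n_features))
  planted <- seq_len(n_planted)
  enet_response <- F[, planted, drop = FALSE] %*% rep(beta_planted, n_planted) +
    stats::rnorm(n, 0, sd_feature_noise)
  enet_response <- drop(enet_response)

  list(expression = expr, sensitivity = outcome, exposure = exposure,
       mediator = mediator, features = F, enet_response = enet_response,
       truth = list(a = a, b = b, c_direct = c_direct,
                    planted = colnames(F)[planted],
                    beta_planted = beta_planted, seed = seed))
}

#' Default decatenation assay dose ladder
#'
#' Nine geometric doses spanning 1.734-400 µM (dilution ratio ~1.97).
#' @return numeric vector of doses in µM, ascending.
#' @export
decat_dose_ladder <- function() {
  exp(seq(log(1.734), log(400), length.out = 9))
}

#' Simulate replicated enzyme decatenation runs
#'
#' Percent decatenation (100 = full activity) for two enzyme paralogs over
#' a shared dose ladder, from decreasing 4PL truths parameterized by their
#' IC25s, with Gaussian noise, over `n_runs` independent runs.
#'
#' @param ic25_A,ic25_B true IC25s (µM) of the two paralogs.
#' @param hill shared hill slope (negative: activity falls with dose).
#' @param noise_sd per-point noise in percent-decatenation points.
#' @param n_runs number of independent runs (default 5).
#' @param doses dose ladder (default [decat_dose_ladder()]).
#' @param seed integer seed.
#' @return list: `decat` (long data frame `run`, `enzyme`, `dose_uM`,
#'   `percent_decatenation`), `truth`.
#' @export
simulate_decatenation <- function(ic25_A = 30, ic25_B = 10, hill = -1,
                                  noise_sd = 5, n_runs = 5,
                                  doses = decat_dose_ladder(), seed = 1) {
  set.seed(seed)
  # IC25 = ec50 * 3^(1/hill) at f = 0.75, so ec50 = IC25 / 3^(1/hill)
  ec50_from_ic25 <- function(ic25) ic25 / 3^(1 / hill)
  truthA <- fourpl_value(doses, 0, 100, hill, ec50_from_ic25(ic25_A))
  truthB <- fourpl_value(doses, 0, 100, hill, ec50_from_ic25(ic25_B))
  rows <- list()
  for (r in seq_len(n_runs)) {
    rows[[length(rows) + 1]] <- data.frame(
      run = r, enzyme = "TOP2A", dose_uM = doses,
      percent_decatenation = truthA + stats::rnorm(length(doses), 0, noise_sd))
    rows[[length(rows) + 1]] <- data.frame(
      run = r, enzyme = "TOP2B", dose_uM = doses,
      percent_decatenation = truthB + stats::rnorm(length(doses), 0, noise_sd))
  }
  list(decat = do.call(rbind, rows),
       truth = list(ic25_A = ic25_A, ic25_B = ic25_B, hill = hill,
                    fold_preference = ic25_A / ic25_B,
                    noise_sd = noise_sd, seed = seed))
}

#' Simulate one-compartment plasma PK profiles
#'
#' `C(t) = (dose / volume) * exp(-k t)` with multiplicative lognormal
#' noise, sampled on a 0.5-24 h grid by default. The default elimination
#' rate corresponds to a 3.7 h terminal half-life.
#'
#' @param dose_mgkg dose (mg/kg).
#' @param volume_L_per_kg apparent volume of distribution (L/kg).
#' @param k elimination rate (1/h); default ln(2)/3.7.
#' @param times sampling times (h).
#' @param cv coefficient of variation of the lognormal noise (default
#'   0.1).
#' @param n_subjects number of profiles.
#' @param seed integer seed.
#' @return list: `profiles` (data frame `subject`, `time_h`, `conc_ugL`,
#'   `dose_mgkg`, `route`), `truth` (incl. `t_half`, `c0_ugL`).
#' @export
simulate_pk <- function(dose_mgkg = 5, volume_L_per_kg = 1,
                        k = log(2) / 3.7,
                        times = c(0.5, 1, 2, 4, 8, 24), cv = 0.1,
                        n_subjects = 3, seed = 1) {
  set.seed(seed)
  c0 <- dose_mgkg * 1000 / volume_L_per_kg  # µg/L
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  rows <- lapply(seq_len(n_subjects), function(s) {
    mu <- c0 * exp(-k * times)
    noise <- if (sdlog > 0)
      exp(stats::rnorm(length(times), -sdlog^2 / 2, sdlog)) else 1
    data.frame(subject = sprintf("M%02d", s), time_h = times,
               conc_ugL = mu * noise, dose_mgkg = dose_mgkg, route = "IV")
  })
  list(profiles = do.call(rbind, rows),
       truth = list(k = k, t_half = log(2) / k, c0_ugL = c0, cv = cv,
                    seed = seed))
}
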