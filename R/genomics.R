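#' Multivariate linear association model on log10 IC50
#'
#' Ordinary least squares with per-coefficient two-sided t-tests, overall
#' F-test, and R-squared: the workhorse behind genotype-vs-sensitivity
#' models such as log10(IC50) ~ MYCN amplification + TP53 mutation.
#'
#' @param y response vector (e.g. log10 IC50).
#' @param X design matrix (predictors only; an intercept is added).
#' @return list of class `ols_fit`: `coefficients` (data frame with
#'   estimate, se, t, p, 95% CI), `r_squared`, `f_p_value`, `sigma`, `n`,
#'   and the underlying `lm` object.
#' @export
ols_fit <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(y) == nrow(X))
  if (length(y) <= ncol(X) + 1) stop("need n > p")
  fit <- stats::lm(y ~ ., data = data.frame(y = y, X, check.names = FALSE))
  if (anyNA(stats::coef(fit))) stop("collinear design")
  sm <- summary(fit)
  cf <- sm$coefficients
  ci <- stats::confint(fit, level = 0.95)
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                      t = cf[, 3], p = cf[, 4],
                      ci_lo = ci[, 1], ci_hi = ci[, 2], row.names = NULL)
  fstat <- sm$fstatistic
  fp <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(coefficients = coefs, r_squared = sm$r.squared,
                 f_p_value = unname(fp), sigma = sm$sigma,
                 n = length(y), lm = fit),
            class = "ols_fit")
}

#' Directional fold-change effect from a log10 IC50 coefficient
#'
#' A coefficient b on the log10 IC50 scale corresponds to a 10^|b|-fold
#' change in IC50: an increase (resistance) when b > 0, a decrease
#' (sensitization) when b < 0. The confidence interval is transformed
#' monotonically onto the same fold scale.
#'
#' @param coefficient coefficient on log10 IC50.
#' @param ci optional length-2 confidence interval for the coefficient.
#' @return list: `fold` (> 0), `direction` (`"increase"`/`"decrease"`/
#'   `"none"`), and `fold_ci` when `ci` was supplied.
#' @export
ic50_fold_effect <- function(coefficient, ci = NULL) {
  stopifnot(is.finite(coefficient))
  direction <- if (coefficient > 0) "increase"
               else if (coefficient < 0) "decrease" else "none"
  s <- if (coefficient < 0) -1 else 1
  out <- list(fold = 10^abs(coefficient), direction = direction)
  if (!is.null(ci)) out$fold_ci <- sort(10^(s * ci))
  out
}

#' Genome-wide Spearman scan of expression vs drug sensitivity
#'
#' Spearman rank correlation of each gene's expression with a sensitivity
#' vector (conventionally 1/IC50, so positive rho = expression tracks
#' sensitivity), with the t-approximation p-value and mean ranks for ties.
#' Constant genes are reported with `NA` (rho undefined).
#'
#' @param expr genes x samples numeric matrix with gene rownames.
#' @param sensitivity numeric vector, one value per sample (column).
#' @return data frame with `gene`, `rho`, `p`, sorted as in `expr`.
#' @export
expression_sensitivity_scan <- function(expr, sensitivity) {
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) == length(sensitivity))
  ok <- is.finite(sensitivity)
  if (sum(ok) < 5) stop("need >= 5 paired samples")
  s <- sensitivity[ok]
  rs <- rank(s)
  n <- length(s)
  res <- t(apply(expr[, ok, drop = FALSE], 1, function(g) {
    if (!all(is.finite(g)) || stats::sd(g) == 0) return(c(NA_real_, NA_real_))
    rho <- stats::cor(rank(g), rs)
    if (abs(rho) >= 1) return(c(rho, 0))
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    c(rho, 2 * stats::pt(-abs(tt), df = n - 2))
  }))
  data.frame(gene = rownames(expr), rho = res[, 1], p = res[, 2],
             row.names = NULL)
}

#' Test whether a gene set's correlations are shifted vs the rest
#'
#' Two-sided t-test comparing per-gene correlation coefficients inside a
#' gene set against the complement. Default is an unpaired Welch test; a
#' paired mode is available but requires an explicit pairing of set genes
#' to complement genes.
#'
#' @param per_gene_rhos numeric vector of per-gene correlations.
#' @param set_membership logical vector, TRUE for set members.
#' @param mode `"unpaired"` (default) or `"paired"`.
#' @param pairing for paired mode: 2-column matrix of indices into
#'   `per_gene_rhos` (set gene, matched complement gene).
#' @return two-sided p-value, with the t statistic as attribute `t`.
#' @export
gene_set_shift_test <- function(per_gene_rhos, set_membership,
                                mode = c("unpaired", "paired"),
                                pairing = NULL) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (is.null(pairing)) stop("pairing required for paired mode")
    pairing <- as.matrix(pairing)
    tt <- stats::t.test(per_gene_rhos[pairing[, 1]],
                        per_gene_rhos[pairing[, 2]], paired = TRUE)
  } else {
    a <- per_gene_rhos[set_membership]
    b <- per_gene_rhos[!set_membership]
    if (length(a) == 0 || length(b) == 0) {
      stop("set and complement must both be non-empty")
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
  }
  structure(tt$p.value, t = unname(tt$statistic))
}

#' Regression-based mediation analysis
#'
#' Fits the marginal model `y ~ exposure` and the joint model
#' `y ~ exposure + mediator`. Full mediation manifests as a significant
#' marginal exposure effect that is lost (p large) once the mediator is
#' conditioned on, while the mediator's conditional effect stays
#' significant.
#'
#' @param sensitivity outcome vector (e.g. log10 IC50 or 1/IC50).
#' @param exposure_expr exposure expression vector (e.g. MYCN).
#' @param mediator_expr candidate mediator expression vector (e.g. TOP2B).
#' @return list of class `mediation_result`: `marginal` (exposure coef,
#'   p), `conditional` (exposure and mediator coefs and p's with the
#'   mediator included), `n`.
#' @export
mediation <- function(sensitivity, exposure_expr, mediator_expr) {
  ok <- is.finite(sensitivity) & is.finite(exposure_expr) &
    is.finite(mediator_expr)
  if (sum(ok) < 10) stop("need >= 10 complete triples")
  y <- sensitivity[ok]; e <- exposure_expr[ok]; m <- mediator_expr[ok]
  if (abs(stats::cor(e, m)) > 0.999) stop("collinear mediator")
  fm <- summary(stats::lm(y ~ e))$coefficients
  fj <- summary(stats::lm(y ~ e + m))$coefficients
  structure(list(
    marginal = list(exposure_coef = fm["e", 1], exposure_p = fm["e", 4]),
    conditional = list(exposure_coef = fj["e", 1], exposure_p = fj["e", 4],
                       mediator_coef = fj["m", 1], mediator_p = fj["m", 4]),
    n = sum(ok)),
    class = "mediation_result")
}

#' ElasticNet regression with cross-validated penalty
#'
#' Penalized regression minimizing
#' \deqn{(1/2n)\,\|y - \beta_0 - X\beta\|^2 +
#'   \lambda(\alpha\|\beta\|_1 + (1-\alpha)\|\beta\|_2^2 / 2)}
#' on standardized features with an unpenalized intercept, the mixing
#' parameter fixed (default `alpha = 0.5`) and `lambda` chosen to minimize
#' the mean k-fold cross-validation error with seeded folds. Fitting is
#' delegated to \pkg{glmnet}; coefficients are returned on the original
#' feature scale.
#'
#' @param X samples x features numeric matrix.
#' @param y response vector (e.g. log2 TOP2B expression).
#' @param alpha L1/L2 mixing parameter (default 0.5).
#' @param k number of CV folds (default 10).
#' @param lambda optional decreasing lambda grid; `NULL` lets glmnet
#'   derive one.
#' @param seed integer seed for the fold assignment.
#' @param standardize standardize features before penalization
#'   (default TRUE).
#' @return list of class `elasticnet_result`: `coefficients` (named,
#'   incl. intercept), `selected` (nonzero features), `lambda`,
#'   `cv_curve` (data frame lambda/cvm/cvsd), `alpha`,
#'   `dropped_features`, and the `cv.glmnet` object.
#' @export
elasticnet_cv <- function(X, y, alpha = 0.5, k = 10, lambda = NULL,
                          seed = 1, standardize = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  if (n < k) stop("too few samples for k folds")
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance features: ",
            paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  set.seed(seed)
  foldid <- sample(rep(seq_len(k), length.out = n))
  cv <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                          lambda = lambda, standardize = standardize,
                          thresh = 1e-12, family = "gaussian")
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
  selected <- names(cf)[cf != 0 & names(cf) != "(Intercept)"]
  structure(list(coefficients = cf, selected = selected,
                 lambda = cv$lambda.min,
                 cv_curve = data.frame(lambda = cv$lambda, cvm = cv$cvm,
                                       cvsd = cv$cvsd),
                 alpha = alpha, dropped_features = dropped, cv = cv),
            class = "elasticnet_result")
}

#' ElasticNet fit at fixed lambda
#'
#' Convenience wrapper around [glmnet::glmnet()] for a single (alpha,
#' lambda) pair with tight convergence, e.g. for limit checks
#' (`lambda = 0` reduces to least squares when n > p; large lambda gives
#' the all-zero solution).
#'
#' @inheritParams elasticnet_cv
#' @param lambda a single penalty value.
#' @return named coefficient vector (incl. intercept).
#' @export
elasticnet_fit <- function(X, y, alpha = 0.5, lambda,
                           standardize = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  lam_path <- sort(unique(c(lambda, lambda + c(4, 2, 1, 0.5) *
                              max(lambda, 0.01))), decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = lam_path,
                        standardize = standardize, thresh = 1e-14,
                        family = "gaussian")
  as.matrix(stats::coef(fit, s = lambda))[, 1]
}

#' Housekeeping-normalized expression
#'
#' log2 fold change of a gene relative to housekeeping genes:
#' `log2(TPM_gene + 1) - mean_hk log2(TPM_hk + 1)` per sample, mitigating
#' dataset-specific effects when comparing expression across cohorts.
#'
#' @param expr genes x samples TPM matrix (>= 0) with gene rownames.
#' @param gene gene to normalize.
#' @param housekeeping housekeeping gene set (default ACTB and GAPDH).
#' @return named numeric vector, one value per sample.
#' @export
housekeeping_normalize <- function(expr, gene,
                                   housekeeping = c("ACTB", "GAPDH")) {
  expr <- as.matrix(expr)
  if (!gene %in% rownames(expr)) stop("gene absent from expression table")
  missing_hk <- setdiff(housekeeping, rownames(expr))
  if (length(missing_hk)) {
    stop("housekeeping gene absent: ", paste(missing_hk, collapse = ", "))
  }
  g <- log2(expr[gene, ] + 1)
  hk <- colMeans(log2(expr[housekeeping, , drop = FALSE] + 1))
  g - hk
}

#' Fold range of a positive vector
#'
#' Ratio of the maximum to the minimum, e.g. the dynamic range of a
#' gene's TPM expression across patient tumors.
#'
#' @param values positive numeric vector, length >= 2.
#' @return max(values) / min(values).
#' @examples
#' fold_range(c(27.8, 405.2))  # ~14.57
#' @export
fold_range <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need >= 2 values")
  if (any(values <= 0)) stop("non-positive expression")
  max(values) / min(values)
}
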