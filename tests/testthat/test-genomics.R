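test_that("OLS matches the normal equations and is exchangeable", {
  # exact linear data -> exact coefficients, R^2 = 1
  X <- cbind(a = c(0, 1, 2, 3, 4), b = c(1, 0, 1, 0, 1))
  y <- 2 + 3 * X[, 1] - 1.5 * X[, 2]
  f <- suppressWarnings(ols_fit(y, X))  # exact fit warns harmlessly
  expect_equal(f$coefficients$estimate, c(2, 3, -1.5), tolerance = 1e-10)
  expect_equal(f$r_squared, 1)
  # 4-point bivariate case vs hand-solved normal equations
  X2 <- cbind(x1 = c(1, 2, 3, 5), x2 = c(0, 1, 0, 1))
  y2 <- c(1.2, 2.9, 3.1, 6.4)
  f2 <- ols_fit(y2, X2)
  Xd <- cbind(1, X2)
  beta_hand <- solve(t(Xd) %*% Xd, t(Xd) %*% y2)
  expect_equal(f2$coefficients$estimate, unname(drop(beta_hand)),
               tolerance = 1e-12)
  # permuting rows changes nothing
  p <- c(3, 1, 4, 2)
  f3 <- ols_fit(y2[p], X2[p, ])
  expect_equal(f3$coefficients, f2$coefficients, tolerance = 1e-12)
  # collinear design errors
  X6 <- cbind(x1 = c(1, 2, 3, 5, 7, 8), x2 = c(0, 1, 0, 1, 1, 0))
  y6 <- c(1.2, 2.9, 3.1, 6.4, 8.8, 8.1)
  expect_error(ols_fit(y6, cbind(X6, x3 = X6[, 1] * 2)), "collinear")
})

test_that("fold-change effects transform coefficients monotonically", {
  expect_equal(ic50_fold_effect(0)$fold, 1)
  expect_equal(ic50_fold_effect(1)$fold, 10)
  expect_equal(ic50_fold_effect(1)$direction, "increase")
  e <- ic50_fold_effect(-log10(10.9), ci = c(-1.2, -0.9))
  expect_equal(e$fold, 10.9)
  expect_equal(e$direction, "decrease")
  expect_true(e$fold_ci[1] <= e$fold && e$fold <= e$fold_ci[2])
})

test_that("Spearman scan matches the rank-covariance definition", {
  s <- c(0.3, 1.2, 0.8, 2.5, 1.9)
  expr <- rbind(up = sort(s) [rank(s)] * 2 + 1,   # strictly increasing with s
                g2 = c(5, 1, 4, 2, 8),
                flat = rep(3, 5))
  res <- expression_sensitivity_scan(expr, s)
  expect_equal(res$rho[1], 1)
  # brute-force rank covariance for g2
  rg <- rank(expr["g2", ]); rs <- rank(s)
  rho_hand <- sum((rg - mean(rg)) * (rs - mean(rs))) /
    sqrt(sum((rg - mean(rg))^2) * sum((rs - mean(rs))^2))
  expect_equal(res$rho[2], rho_hand, tolerance = 1e-12)
  expect_true(is.na(res$rho[3]))  # constant gene undefined
  # invariance under strictly monotone transforms of either variable
  res2 <- expression_sensitivity_scan(expr^3, exp(s))
  expect_equal(res2$rho, res$rho, tolerance = 1e-12)
})

test_that("gene-set shift test has power and calibrated nulls", {
  set.seed(31)
  rhos <- c(rnorm(11, 0.5, 0.1), rnorm(1000, 0, 0.1))
  member <- c(rep(TRUE, 11), rep(FALSE, 1000))
  expect_lt(gene_set_shift_test(rhos, member), 1e-6)
  expect_error(gene_set_shift_test(rhos, rep(FALSE, 1011)), "non-empty")
  expect_error(gene_set_shift_test(rhos, member, mode = "paired"),
               "pairing required")
  # null calibration: rejection rate at alpha = .05 stays near nominal
  set.seed(32)
  rej <- mean(replicate(500, {
    x <- rnorm(70)
    gene_set_shift_test(x, seq_along(x) <= 20) < 0.05
  }))
  expect_lte(rej, 0.07)
})

test_that("mediation separates direct from mediated structures", {
  # mediator independent of exposure, noiseless direct effect:
  # conditional exposure coefficient equals the marginal one
  set.seed(41)
  e <- rnorm(30); m <- rnorm(30)
  y <- 2 * e
  r <- suppressWarnings(mediation(y, e, m))  # exact fit warns
  expect_equal(r$conditional$exposure_coef, r$marginal$exposure_coef,
               tolerance = 1e-10)
  expect_error(mediation(y, e, e + 1e-9 * m), "collinear mediator")
  expect_error(mediation(y[1:5], e[1:5], m[1:5]), "complete triples")
  # full mediation: conditional exposure association lost, mediator retained
  sim <- simulate_expression_chain(n_samples = 29, c_direct = 0, seed = 42)
  r2 <- mediation(sim$sensitivity, sim$exposure, sim$mediator)
  expect_lt(r2$marginal$exposure_p, 0.05)
  expect_lt(r2$conditional$mediator_p, 0.01)
})

test_that("elastic net limits: full shrinkage and the OLS end of the path", {
  sim <- simulate_expression_chain(n_samples = 88, seed = 51)
  X <- sim$features; y <- sim$enet_response
  big <- elasticnet_fit(X, y, alpha = 0.5, lambda = 100)
  expect_true(all(big[-1] == 0))
  ols <- elasticnet_fit(X, y, alpha = 0.5, lambda = 0)
  ref <- coef(lm(y ~ X))
  expect_lt(max(abs(unname(ols) - unname(ref))), 1e-6)
})

test_that("cv elastic net selects planted predictors and satisfies KKT", {
  sim <- simulate_expression_chain(n_samples = 88, seed = 52)
  en <- elasticnet_cv(sim$features, sim$enet_response, alpha = 0.5, k = 10,
                      seed = 52)
  expect_true(all(sim$truth$planted %in% en$selected))
  # KKT on the standardized problem at the chosen lambda, under the
  # penalty convention actually fit (the ridge term carries a 1/sd(y)
  # factor from the response standardization)
  y <- sim$enet_response
  sy <- sqrt(mean((y - mean(y))^2))
  Xs <- standardize_1n(sim$features)
  cf <- elasticnet_fit(Xs, y, alpha = 0.5, lambda = en$lambda,
                       standardize = FALSE)
  kkt <- oracle_enet_kkt(Xs, y, cf[1], cf[-1],
                         l1 = en$lambda * 0.5, l2 = en$lambda * 0.5 / sy)
  expect_lt(kkt, 1e-6)
  # objective matches an exhaustive coordinate-descent oracle on the
  # 3-feature planted sub-problem
  Xsub <- Xs[, 1:3]
  lam <- 0.05
  cf3 <- elasticnet_fit(Xsub, y, alpha = 0.5, lambda = lam,
                        standardize = FALSE)
  or <- oracle_enet_cd(Xsub, y, l1 = lam * 0.5, l2 = lam * 0.5 / sy)
  obj_pkg <- oracle_enet_objective(Xsub, y, cf3[1], cf3[-1],
                                   l1 = lam * 0.5, l2 = lam * 0.5 / sy)
  obj_or <- oracle_enet_objective(Xsub, y, or$b0, or$beta,
                                  l1 = lam * 0.5, l2 = lam * 0.5 / sy)
  expect_lt(abs(obj_pkg - obj_or), 1e-8)
  expect_error(elasticnet_cv(sim$features[1:5, ], sim$enet_response[1:5]),
               "too few samples")
})

test_that("housekeeping normalization does its log arithmetic", {
  expr <- rbind(TOP2B = c(1000, 4000, 132.4),
                ACTB = c(1000, 1000, 1500),
                GAPDH = c(1000, 1000, 2000))
  v <- housekeeping_normalize(expr, "TOP2B")
  expect_equal(v[[1]], 0, tolerance = 1e-3)
  expect_equal(v[[2]], 2, tolerance = 1e-3)
  # hand-computed third sample
  hand <- log2(132.4 + 1) - mean(c(log2(1501), log2(2001)))
  expect_equal(v[[3]], hand, tolerance = 1e-12)
  expect_error(housekeeping_normalize(expr[1:2, ], "TOP2B"),
               "housekeeping gene absent")
})

test_that("fold range is max over min on positive vectors", {
  expect_equal(fold_range(c(1, 2, 8)), 8)
  expect_equal(fold_range(c(5, 5, 5)), 1)
  expect_error(fold_range(c(-1, 2)), "non-positive")
})
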