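# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force Selectivity Score: exhaustive sort, hand-computed mean ranks
# for ties, median of target ranks.
oracle_selectivity <- function(ic50, is_target) {
  n <- length(ic50)
  srt <- sort(ic50)
  rk <- vapply(ic50, function(v) mean(which(srt == v)), numeric(1))
  tr <- sort(unname(rk[is_target]))
  m <- length(tr)
  med <- if (m %% 2 == 1) tr[(m + 1) / 2] else mean(tr[c(m / 2, m / 2 + 1)])
  list(score = med / n, median_rank = med)
}

# Bisection root-finder for the dose at which a 4PL fit reaches `effect`.
oracle_bisect_icx <- function(fit, effect, lo = 1e-12, hi = 1e12,
                              tol = 1e-12) {
  f <- function(d) predict(fit, d) - effect
  llo <- log(lo); lhi <- log(hi)
  if (sign(f(exp(llo))) == sign(f(exp(lhi)))) stop("no bracket")
  for (i in 1:200) {
    mid <- (llo + lhi) / 2
    if (sign(f(exp(mid))) == sign(f(exp(llo)))) llo <- mid else lhi <- mid
    if (lhi - llo < tol) break
  }
  exp((llo + lhi) / 2)
}

# Cyclic coordinate descent for the elastic net
#   (1/2n)||y - b0 - X b||^2 + l1 |b|_1 + l2 |b|^2 / 2
# on raw (already standardized by the caller) X. l1 = lambda * alpha and
# l2 = lambda * (1 - alpha) gives the textbook parameterization; the
# glmnet gaussian convention (internal response standardization) further
# divides l2 by the 1/n-convention sd of y.
oracle_enet_cd <- function(X, y, l1, l2, n_iter = 10000, tol = 1e-14) {
  n <- nrow(X); p <- ncol(X)
  b <- rep(0, p); b0 <- mean(y)
  r <- y - b0
  xss <- colSums(X^2) / n
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (it in seq_len(n_iter)) {
    b_old <- b
    for (j in seq_len(p)) {
      zj <- sum(X[, j] * r) / n + xss[j] * b[j]
      bj <- soft(zj, l1) / (xss[j] + l2)
      if (bj != b[j]) {
        r <- r - X[, j] * (bj - b[j])
        b[j] <- bj
      }
    }
    b0_new <- b0 + mean(r)
    r <- r - (b0_new - b0)
    b0 <- b0_new
    if (max(abs(b - b_old)) < tol) break
  }
  list(b0 = b0, beta = b)
}

oracle_enet_objective <- function(X, y, b0, beta, l1, l2) {
  n <- nrow(X)
  r <- y - b0 - drop(X %*% beta)
  sum(r^2) / (2 * n) + l1 * sum(abs(beta)) + l2 * sum(beta^2) / 2
}

# KKT (subgradient stationarity) residual of an elastic-net solution on
# standardized X.
oracle_enet_kkt <- function(X, y, b0, beta, l1, l2) {
  n <- nrow(X)
  r <- y - b0 - drop(X %*% beta)
  grad <- -colSums(X * r) / n + l2 * beta
  resid <- numeric(length(beta))
  nz <- beta != 0
  resid[nz] <- abs(grad[nz] + l1 * sign(beta[nz]))
  resid[!nz] <- pmax(abs(grad[!nz]) - l1, 0)
  max(c(resid, abs(mean(r))))
}

# standardize columns with 1/n variance (glmnet's convention)
standardize_1n <- function(X) {
  n <- nrow(X)
  xm <- colMeans(X)
  xs <- sqrt(colMeans(scale(X, center = TRUE, scale = FALSE)^2))
  scale(X, center = xm, scale = xs)
}
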