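# One-way grouping kernel: K[a, b] = 1 iff a, b share a group.
group_kernel <- function(grp) outer(grp, grp, `==`) * 1.0

# Independent 1-D oracle: profile the restricted likelihood over the
# variance ratio r = sigma2_k / sigma2_e on a log grid.
grid_reml_ratio <- function(y, K, grid = 10^seq(-4, 4, length.out = 4001)) {
  n <- length(y)
  ll <- vapply(grid, function(r) {
    V <- r * K + diag(n)
    Vi <- solve(V)
    mu <- sum(Vi %*% y) / sum(Vi)
    q <- drop(t(y - mu) %*% Vi %*% (y - mu))
    s2 <- q / (n - 1)
    -0.5 * (determinant(V)$modulus + (n - 1) * log(s2) +
              log(sum(Vi)) + (n - 1))
  }, numeric(1))
  grid[which.max(ll)]
}

test_that("intercept-only fits reduce to the sample mean", {
  y <- c(3, NA, 5, 7, NA)
  fit <- fit_gblup(y, list())
  expect_equal(fit$mu, 5)
  expect_equal(fit$fitted, rep(5, 5))
  expect_equal(predict(fit), c(5, 5))
})

test_that("REML matches a 1-D grid-search likelihood oracle", {
  set.seed(11)
  grp <- rep(1:6, each = 4)
  y <- 2 + rnorm(6, 0, 1.1)[grp] + rnorm(length(grp), 0, 0.9)
  K <- group_kernel(grp)
  fit <- fit_gblup(y, list(g = K))
  r_fit <- fit$components[["g"]] / fit$components[["residual"]]
  r_grid <- grid_reml_ratio(y, K)
  expect_lt(abs(r_fit - r_grid) / r_grid, 0.01)
})

test_that("with fixed components, predictions equal the kernel-ridge closed form", {
  set.seed(21)
  n <- 10
  X <- matrix(rnorm(n * 6), n)
  K <- tcrossprod(scale(X, scale = FALSE))
  K <- K / mean(diag(K))
  y <- rnorm(n)
  y[c(2, 7, 9)] <- NA
  s2g <- 2
  s2e <- 1
  fit <- fit_gblup(y, list(k = K), fix = c(k = s2g, residual = s2e))
  obs <- !is.na(y)
  lam <- s2e / s2g
  Vi <- solve(K[obs, obs] + lam * diag(sum(obs)))
  one <- rep(1, sum(obs))
  mu <- drop(crossprod(one, Vi %*% y[obs]) / crossprod(one, Vi %*% one))
  ridge <- drop(mu + K[, obs] %*% Vi %*% (y[obs] - mu))
  expect_lt(max(abs(fit$fitted - ridge)), 1e-8)
  expect_equal(fit$components[["k"]], s2g)
})

test_that("variance components are recovered on simulated data", {
  est <- matrix(NA_real_, 6, 2)
  for (s in 1:6) {
    G <- small_grm(200, 300, seed = 30 + s)
    set.seed(60 + s)
    u <- drop(t(chol(G + 1e-6 * diag(200))) %*% rnorm(200)) * sqrt(2)
    y <- 5 + u + rnorm(200, 0, 1)
    fit <- fit_gblup(y, list(g = unname(G)))
    est[s, ] <- fit$components
  }
  avg <- colMeans(est)
  expect_lt(abs(avg[1] - 2) / 2, 0.3)
  expect_lt(abs(avg[2] - 1) / 1, 0.3)
})

test_that("fits are scale- and permutation-equivariant", {
  set.seed(31)
  n <- 40
  grp <- rep(1:8, each = 5)
  K <- group_kernel(grp)
  y <- 1 + rnorm(8)[grp] + rnorm(n, 0, 0.7)
  y[c(3, 25)] <- NA
  fit1 <- fit_gblup(y, list(g = K))
  # scale equivariance at c = 10
  fit10 <- fit_gblup(10 * y, list(g = K))
  expect_equal(fit10$mu, 10 * fit1$mu, tolerance = 1e-6)
  expect_equal(fit10$components, 100 * fit1$components, tolerance = 1e-6)
  expect_equal(fit10$fitted, 10 * fit1$fitted, tolerance = 1e-6)
  # permutation equivariance
  perm <- sample(n)
  fitp <- fit_gblup(y[perm], list(g = K[perm, perm]))
  expect_equal(fitp$fitted, fit1$fitted[perm], tolerance = 1e-6)
  expect_equal(fitp$components, fit1$components, tolerance = 1e-6)
})

test_that("the restricted log-likelihood never decreases across iterations", {
  set.seed(41)
  G <- small_grm(60, 80, seed = 3)
  y <- drop(t(chol(G + 1e-6 * diag(60))) %*% rnorm(60)) + rnorm(60, 0, 0.5)
  H <- env_kernel(rep(c("a", "b", "c"), each = 20))
  fit <- fit_gblup(y, list(g = unname(G), e = H))
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("held-out observations cannot influence the fit", {
  # Identical training data with different held-out truths must produce an
  # identical FitResult (the held-out values are masked before fitting).
  Y <- rand_Y(15, 3, seed = 51)
  G <- small_grm(15, 40, seed = 52)
  rownames(G) <- colnames(G) <- rownames(Y)
  p1 <- fit_m1(toy_phenos(Y), G, "E2")
  Y2 <- Y
  Y2[, "E2"] <- Y2[, "E2"] + rnorm(15, 0, 10)
  p2 <- fit_m1(toy_phenos(Y2), G, "E2")
  expect_identical(p1$predicted, p2$predicted)
  expect_false(identical(p1$observed, p2$observed))
})

test_that("degenerate and invalid inputs are handled explicitly", {
  expect_error(fit_gblup(c(1, Inf, 2), list()), "non-finite")
  expect_error(fit_gblup(c(1, NA), list()), "at least 2")
  K <- diag(3)
  expect_error(fit_gblup(1:3, list(K)), "named")
  expect_error(fit_gblup(1:3, list(residual = K)), "reserved")
  expect_error(fit_gblup(1:4, list(g = K)), "n x n")
  # constant response: intercept carries everything, BLUPs vanish
  fit <- fit_gblup(rep(4, 6), list(g = group_kernel(rep(1:2, 3))))
  expect_equal(fit$fitted, rep(4, 6))
  expect_equal(unname(fit$components[["g"]]), 0)
})

test_that("the Gibbs sampler reproduces itself under a seed and tracks REML", {
  set.seed(61)
  grp <- rep(1:10, each = 6)
  K <- group_kernel(grp)
  y <- 3 + rnorm(10, 0, 1.5)[grp] + rnorm(60, 0, 0.8)
  y[c(2, 30)] <- NA
  expect_error(fit_gblup(y, list(g = K), method = "gibbs"), "seed")
  g1 <- fit_gblup(y, list(g = K), method = "gibbs",
                  gibbs = list(n_iter = 1500, burn_in = 500, seed = 7))
  g2 <- fit_gblup(y, list(g = K), method = "gibbs",
                  gibbs = list(n_iter = 1500, burn_in = 500, seed = 7))
  expect_identical(g1$fitted, g2$fitted)
  r <- fit_gblup(y, list(g = K))
  expect_gt(cor(g1$fitted, r$fitted), 0.98)
  expect_lt(abs(g1$mu - r$mu), 0.5)
})

test_that("gblup S3 methods are coherent", {
  set.seed(71)
  K <- group_kernel(rep(1:4, each = 3))
  y <- rnorm(12)
  y[1] <- NA
  fit <- fit_gblup(y, list(g = K))
  expect_equal(fitted(fit), fit$mu + rowSums(fit$blups))
  expect_equal(coef(fit), c(`(Intercept)` = fit$mu))
  expect_equal(residuals(fit)[-1], (y - fitted(fit))[-1])
  expect_true(is.na(residuals(fit)[1]))
  expect_equal(predict(fit, rep(TRUE, 12)), fit$fitted)
  expect_error(predict(fit, c(TRUE, FALSE)), "length")
  expect_equal(predict(fit, rep(FALSE, 12)), numeric(0))
  expect_output(print(fit), "variance components")
  expect_output(print(summary(fit)), "Intercept")
  expect_s3_class(logLik(fit), "logLik")
})
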