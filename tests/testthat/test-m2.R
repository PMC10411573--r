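test_that("environment pairs enumerate in canonical order", {
  p <- enumerate_env_pairs(c("E1", "E2", "E3"))
  expect_equal(p$env_i, c("E1", "E1", "E2"))
  expect_equal(p$env_iprime, c("E2", "E3", "E3"))
  expect_equal(nrow(enumerate_env_pairs(c("A", "B"))), 1L)
  p6 <- enumerate_env_pairs(paste0("E", 1:6))
  expect_equal(nrow(p6), choose(6, 2))
  # exhaustive check: every unordered pair appears exactly once
  key <- paste(pmin(p6$env_i, p6$env_iprime), pmax(p6$env_i, p6$env_iprime))
  expect_equal(sort(key),
               sort(apply(combn(paste0("E", 1:6), 2), 2, paste,
                          collapse = " ")))
  expect_error(enumerate_env_pairs(c("E1", "E1")), "duplicate")
})

test_that("the stacked difference frame has the published layout", {
  Y <- rand_Y(3, 3, seed = 1)
  fr <- difference_frame(toy_phenos(Y))
  expect_s3_class(fr, "diff_frame")
  expect_equal(nrow(fr), 9L)
  expect_equal(fr$obs, 1:9)
  expect_equal(fr$line, rep(paste0("g", 1:3), 3))
  expect_equal(fr$env_i, rep(c("E1", "E1", "E2"), each = 3))
  expect_equal(fr$env_iprime, rep(c("E2", "E3", "E3"), each = 3))
  expect_equal(fr$d, fr$y_i - fr$y_iprime)
  expect_equal(fr$y_i, unname(c(Y[, 1], Y[, 1], Y[, 2])))
  expect_equal(fr$y_iprime, unname(c(Y[, 2], Y[, 3], Y[, 3])))
})

test_that("difference values follow d = y_i - y_iprime on a hand example", {
  Y <- rbind(g1 = c(1, 3, 0), g2 = c(2, 5, 0))
  colnames(Y) <- paste0("E", 1:3)
  fr <- difference_frame(toy_phenos(Y))
  expect_equal(fr$d, c(-2, -3, 1, 2, 3, 5))
  # identical phenotypes across environments: all differences zero
  Yc <- matrix(4, 3, 3, dimnames = list(paste0("g", 1:3), paste0("E", 1:3)))
  expect_true(all(difference_frame(toy_phenos(Yc))$d == 0))
})

test_that("the row-count law J * choose(I, 2) holds across designs", {
  for (J in c(2, 5, 10)) for (I in 3:6) {
    Y <- rand_Y(J, I, seed = J * 10 + I)
    fr <- difference_frame(toy_phenos(Y))
    expect_equal(nrow(fr), J * choose(I, 2))
    for (e in colnames(Y)) {
      m <- mask_target_env(fr, e)
      expect_equal(sum(is.na(m$d)), J * (I - 1))
    }
  }
  expect_error(difference_frame(toy_phenos(rand_Y(4, 2, seed = 1))),
               "at least 3")
})

test_that("masking the target environment matches the published scheme", {
  Y <- rand_Y(3, 3, seed = 2)
  fr <- difference_frame(toy_phenos(Y))
  m <- mask_target_env(fr, "E1")
  expect_true(all(is.na(m$d[1:6])))
  expect_equal(m$d[7:9], fr$d[7:9])
  expect_error(mask_target_env(fr, "E9"), "not present")
  # I = 4, target E2: pairs (E1,E2), (E2,E3), (E2,E4) -> 3 J masked rows
  Y4 <- rand_Y(5, 4, seed = 3)
  m4 <- mask_target_env(difference_frame(toy_phenos(Y4)), "E2")
  expect_equal(sum(is.na(m4$d)), 5 * 3)
})

test_that("the difference model predicts zero when training differences are zero", {
  Y <- matrix(rep(rnorm(6), 3), 6, 3,
              dimnames = list(paste0("g", 1:6), paste0("E", 1:3)))
  G <- small_grm(6, 30, seed = 4)
  rownames(G) <- colnames(G) <- rownames(Y)
  fr <- mask_target_env(difference_frame(toy_phenos(Y)), "E1")
  d_hat <- fit_difference_model(fr, G)
  expect_lt(max(abs(d_hat)), 1e-8)
})

test_that("with fixed components the difference model equals the ridge oracle", {
  Y <- rand_Y(3, 3, seed = 5)
  G <- small_grm(3, 30, seed = 6)
  rownames(G) <- colnames(G) <- rownames(Y)
  fr <- mask_target_env(difference_frame(toy_phenos(Y)), "E1")
  d_hat <- fit_difference_model(fr, G, fix = c(line = 1.5, residual = 0.5))
  train <- !is.na(fr$d)
  Ktr <- G[fr$line[train], fr$line[train]]
  Kcross <- G[fr$line[!train], fr$line[train]]
  lam <- 0.5 / 1.5
  Vi <- solve(Ktr + lam * diag(sum(train)))
  one <- rep(1, sum(train))
  mu <- drop(crossprod(one, Vi %*% fr$d[train]) /
               crossprod(one, Vi %*% one))
  oracle <- drop(mu + Kcross %*% Vi %*% (fr$d[train] - mu))
  expect_equal(as.numeric(d_hat), unname(oracle), tolerance = 1e-8)
})

test_that("the ensemble reproduces the worked numeric example", {
  fr <- structure(
    data.frame(obs = 1:3, line = "g1",
               env_i = c("E1", "E1", "E2"),
               env_iprime = c("E2", "E3", "E3"),
               y_i = c(NA, NA, 5.0), y_iprime = c(5.0, 7.0, 7.0),
               d = c(NA, NA, -2.0), stringsAsFactors = FALSE),
    class = c("diff_frame", "data.frame"))
  pr <- ensemble_from_differences(fr, c(1.0, -0.5), "E1")
  expect_equal(pr$predicted, ((5.0 + 1.0) + (7.0 - 0.5)) / 2)
  expect_equal(pr$model, "M2")
  expect_error(ensemble_from_differences(fr, c(1.0), "E1"), "length")
})

test_that("a single pair reduces the ensemble to one signed term", {
  # I = 2 frame built directly (the guard in difference_frame is stricter)
  fr <- structure(
    data.frame(obs = 1:2, line = c("g1", "g2"),
               env_i = "E1", env_iprime = "E2",
               y_i = c(NA, NA), y_iprime = c(2.0, 3.0),
               d = c(NA, NA), stringsAsFactors = FALSE),
    class = c("diff_frame", "data.frame"))
  pr <- ensemble_from_differences(fr, c(0.5, -1.0), "E1")
  expect_equal(pr$predicted, c(2.5, 2.0))
  # target as the second pair element uses y_i - d_hat
  fr2 <- fr
  fr2$env_i <- "E2"; fr2$env_iprime <- "E1"
  fr2$y_i <- c(2.0, 3.0); fr2$y_iprime <- c(NA, NA)
  pr2 <- ensemble_from_differences(fr2, c(0.5, -1.0), "E1")
  expect_equal(pr2$predicted, c(1.5, 4.0))
})

test_that("perfect difference predictions recover the target exactly", {
  for (seed in 1:3) {
    J <- sample(5:50, 1)
    I <- sample(3:6, 1)
    Y <- rand_Y(J, I, seed = 600 + seed)
    target <- sample(colnames(Y), 1)
    fr <- mask_target_env(difference_frame(toy_phenos(Y)), target)
    sub <- fr[is.na(fr$d), ]
    d_true <- Y[cbind(sub$line, sub$env_i)] -
      Y[cbind(sub$line, sub$env_iprime)]
    pr <- ensemble_from_differences(fr, d_true, target)
    expect_lt(max(abs(pr$predicted - Y[pr$line, target])), 1e-12)
  }
})

test_that("swapping a pair's orientation leaves the ensemble unchanged", {
  Y <- rand_Y(4, 3, seed = 7)
  fr <- mask_target_env(difference_frame(toy_phenos(Y)), "E1")
  d_hat <- seq(0.1, 0.8, length.out = 8)
  base <- ensemble_from_differences(fr, d_hat, "E1")
  # flip the (E1, E3) block: negate its d-hat and swap its columns
  flip <- fr$env_i == "E1" & fr$env_iprime == "E3"
  fr2 <- fr
  fr2$env_i[flip] <- "E3"; fr2$env_iprime[flip] <- "E1"
  tmp <- fr2$y_i[flip]
  fr2$y_i[flip] <- fr$y_iprime[flip]; fr2$y_iprime[flip] <- tmp
  d2 <- d_hat
  d2[5:8] <- -d_hat[5:8]  # masked rows 5-8 are the flipped block
  swapped <- ensemble_from_differences(fr2, d2, "E1")
  expect_equal(swapped$predicted, base$predicted, tolerance = 1e-12)
})

test_that("target-environment level shifts cannot reach the predictions", {
  Y <- rand_Y(12, 4, seed = 8)
  G <- small_grm(12, 40, seed = 9)
  rownames(G) <- colnames(G) <- rownames(Y)
  p1 <- fit_m2(toy_phenos(Y), G, "E2")
  Y2 <- Y
  Y2[, "E2"] <- Y2[, "E2"] + 50
  p2 <- fit_m2(toy_phenos(Y2), G, "E2")
  expect_equal(p1$predicted, p2$predicted, tolerance = 1e-10)
  expect_equal(p2$observed - p1$observed, rep(50, 12))
})

test_that("the composed M2 pipeline behaves on degenerate and simulated data", {
  # constant phenotypes -> constant predictions
  Yc <- matrix(3, 6, 3, dimnames = list(paste0("g", 1:6), paste0("E", 1:3)))
  G <- small_grm(6, 30, seed = 10)
  rownames(G) <- colnames(G) <- rownames(Yc)
  pc <- fit_m2(toy_phenos(Yc), G, "E3")
  expect_equal(pc$predicted, rep(3, 6), tolerance = 1e-8)
  expect_error(fit_m2(toy_phenos(rand_Y(4, 2, seed = 1)), G, "E1"),
               "at least 3")

  # difference model predictions carry signal when differences do
  cors <- numeric(4)
  for (s in 1:4) {
    M <- simulate_markers(80, 200, seed = 700 + s)
    sim <- simulate_trial(M, I = 4, var_g = 1, var_env = 0.5, var_ge = 0.5,
                          var_e = 0.3, seed = 800 + s)
    G <- vanraden_grm(M)
    pr <- fit_m2(sim$phenos, G, "E1")
    truth <- sim$truth$genetic[pr$line, "E1"]
    cors[s] <- cor(pr$predicted, truth)
  }
  expect_gt(mean(cors), 0.5)
})
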