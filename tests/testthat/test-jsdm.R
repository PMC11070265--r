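test_that("trend-surface basis has the right monomials and is shift invariant", {
  set.seed(41)
  coords <- cbind(runif(20, 0, 960), runif(20, 0, 960))
  expect_equal(ncol(build_trend_surface(coords, 1)$basis), 2)
  ts2 <- build_trend_surface(coords, 2)
  expect_equal(colnames(ts2$basis), c("x", "y", "x2", "xy", "y2"))
  shifted <- build_trend_surface(coords + 5000, 2)
  expect_equal(shifted$basis, ts2$basis, tolerance = 1e-9)
  expect_error(build_trend_surface(cbind(rep(1, 5), rep(2, 5)), 2),
               "zero variance")
})

test_that("rank-based AUC handles boundaries, ties, and single classes", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0)
  expect_equal(auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_true(is.na(auc(c(0.3, 0.7), c(1, 1))))
})

test_that("rank-0 MC probit loss equals the closed-form independent probit", {
  set.seed(42)
  eta <- matrix(rnorm(30 * 4, sd = 1.5), 30, 4)
  Y <- matrix(rbinom(120, 1, 0.5), 30, 4)
  out <- mc_probit_nll(eta, NULL, Y, M = 7, seed = 3)
  expect_equal(out$value, probit_nll_oracle(eta, Y), tolerance = 1e-12)
  # single observation at eta = 0: -log(1/2)
  expect_equal(mc_probit_nll(matrix(0), NULL, matrix(1))$value,
               -log(0.5), tolerance = 1e-12)
  # gradient check against numerical differentiation
  g <- out$grad_eta[2, 3]
  h <- 1e-5
  etap <- eta; etap[2, 3] <- eta[2, 3] + h
  etam <- eta; etam[2, 3] <- eta[2, 3] - h
  num <- (probit_nll_oracle(etap, Y) - probit_nll_oracle(etam, Y)) / (2 * h)
  expect_equal(g, num, tolerance = 1e-5)
})

test_that("rank-1 MC loss matches latent-variable quadrature within MC error", {
  set.seed(43)
  eta <- matrix(rnorm(6 * 2, sd = 0.8), 6, 2)
  lambda <- c(0.8, -0.5)
  Y <- matrix(rbinom(12, 1, 0.5), 6, 2)
  oracle <- rank1_nll_quadrature(eta, lambda, Y)
  reps <- vapply(1:7, function(s)
    mc_probit_nll(eta, matrix(lambda, 2, 1), Y, M = 1e4, seed = s)$value,
    numeric(1))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - oracle), 3 * se + 1e-4)
})

test_that("MC loss variance shrinks like 1/M", {
  set.seed(44)
  eta <- matrix(rnorm(10 * 3), 10, 3)
  Lam <- matrix(rnorm(3), 3, 1)
  Y <- matrix(rbinom(30, 1, 0.5), 10, 3)
  at_m <- vapply(1:60, function(s)
    mc_probit_nll(eta, Lam, Y, M = 50, seed = s)$value, numeric(1))
  at_4m <- vapply(1:60, function(s)
    mc_probit_nll(eta, Lam, Y, M = 200, seed = 1000 + s)$value, numeric(1))
  ratio <- stats::var(at_m) / stats::var(at_4m)
  expect_gt(ratio, 1.8)   # ~4 in expectation; loose band for 60 reps
  expect_lt(ratio, 9)
})

test_that("rank-0 linear fit agrees with independent probit regressions", {
  set.seed(45)
  n <- 300
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("c", 1:3)))
  B <- matrix(c(1.2, -0.8, 0.0, 0.5, 0.9, -1.1), 3, 2)
  eta <- X %*% B
  Y <- (eta + matrix(rnorm(n * 2), n, 2) > 0) * 1
  colnames(Y) <- c("spA", "spB")
  hp <- jsdm_hyperparams(env_penalty = 1e-6, latent_rank = 0,
                         epochs = 2000, lr = 0.1, trend_degree = 0)
  m <- fit_jsdm(Y, X, coords = NULL, hyper = hp, seed = 1)
  # undo the internal standardization to compare on the raw-covariate scale
  W_raw <- m$params$W_out / m$x_scale
  for (j in 1:2) {
    g <- stats::glm(Y[, j] ~ X, family = binomial("probit"))
    expect_equal(unname(W_raw[, j]), unname(coef(g)[-1]), tolerance = 0.05)
  }
})

test_that("extreme environment penalty shrinks weights to prevalence-only", {
  w <- tiny_world
  hp <- jsdm_hyperparams(env_penalty = 1e5, env_mix = 0.5, latent_rank = 0,
                         epochs = 400, trend_degree = 0)
  m <- fit_jsdm(w$inc$Y, w$X, coords = NULL, hyper = hp, seed = 2)
  expect_lt(sqrt(sum(m$params$W_out^2)), 1e-3)
  P <- predict_prob(m, w$X)
  prev <- colMeans(w$inc$Y)
  expect_equal(unname(colMeans(P)), unname(prev), tolerance = 0.02)
})

test_that("stronger penalties never grow the penalized block norm", {
  w <- tiny_world
  norms <- vapply(c(0.01, 0.1, 1, 10), function(lam) {
    hp <- jsdm_hyperparams(env_penalty = lam, latent_rank = 0,
                           epochs = 300, trend_degree = 0)
    m <- fit_jsdm(w$inc$Y, w$X, coords = NULL, hyper = hp, seed = 3)
    sqrt(sum(m$params$W_out^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("fit is deterministic and predictions respect structure", {
  w <- tiny_world
  hp <- jsdm_hyperparams(latent_rank = 2, epochs = 80, M = 20)
  m1 <- fit_jsdm(w$inc$Y, w$X, w$coords, hp, seed = 7)
  m2 <- fit_jsdm(w$inc$Y, w$X, w$coords, hp, seed = 7)
  expect_identical(m1$params, m2$params)
  P <- predict_prob(m1, w$X, w$coords)
  expect_true(all(P >= 0 & P <= 1))
  # duplicated input row duplicates the output row
  X2 <- w$X[c(1, 1, 2), ]; co2 <- w$coords[c(1, 1, 2), ]
  P2 <- predict_prob(m1, X2, co2)
  expect_identical(P2[1, ], P2[2, ])
  # schema errors name the offending covariates
  Xbad <- w$X[, -2]
  expect_error(predict_prob(m1, Xbad, w$coords), "missing: \\[cov02\\]")
})

test_that("marginal prediction formula matches latent Monte Carlo", {
  w <- tiny_world
  hp <- jsdm_hyperparams(latent_rank = 2, epochs = 60, M = 20,
                         trend_degree = 0)
  m <- fit_jsdm(w$inc$Y, w$X, coords = NULL, hyper = hp, seed = 8)
  P <- predict_prob(m, w$X[1:3, , drop = FALSE])
  Xs <- sweep(sweep(w$X[1:3, , drop = FALSE], 2, m$x_center), 2,
              m$x_scale, "/")
  eta <- sidewaysmap:::net_forward(m$params, Xs)$eta_env
  set.seed(9)
  H <- matrix(rnorm(2e5), ncol = 2)
  for (i in 1:3) for (j in c(1, 4)) {
    draws <- stats::pnorm(eta[i, j] + H %*% m$params$Lambda[j, ])
    se <- stats::sd(draws) / sqrt(nrow(H))
    expect_lt(abs(P[i, j] - mean(draws)), 3 * se + 1e-6)
  }
})

test_that("serialized models round-trip to bit-identical predictions", {
  w <- tiny_world
  hp <- jsdm_hyperparams(latent_rank = 1, hidden = c(8L), epochs = 50,
                         M = 15)
  m <- fit_jsdm(w$inc$Y, w$X, w$coords, hp, seed = 10)
  path <- withr::local_tempfile(fileext = ".json")
  save_jsdm(m, path)
  m2 <- load_jsdm(path)
  expect_identical(predict_prob(m, w$X, w$coords),
                   predict_prob(m2, w$X, w$coords))
  expect_identical(m$params, m2$params)
})

test_that("fit validates its inputs", {
  w <- tiny_world
  expect_error(fit_jsdm(w$inc$Y[, 1, drop = FALSE], w$X), ">= 2 species")
  Xna <- w$X; Xna[3, 2] <- NA
  expect_error(fit_jsdm(w$inc$Y, Xna), "missing")
  Ybad <- w$inc$Y; Ybad[1, 1] <- 2
  expect_error(fit_jsdm(Ybad, w$X), "binary")
})
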