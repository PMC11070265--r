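make_coverage <- function(df) {
  data.frame(sample_id = df$s, species_id = df$o, covered_fraction = df$f,
             stringsAsFactors = FALSE)
}

test_that("call_presences uses a strict >50% barcode-coverage rule", {
  cov <- make_coverage(data.frame(
    s = c("a", "a", "b", "b"), o = c("x", "y", "x", "y"),
    f = c(0.51, 0.50, 0.0, 1.0)))
  inc <- call_presences(cov)
  expect_equal(inc$Y["a", "x"], 1L)  # just above the boundary
  expect_equal(inc$Y["a", "y"], 0L)  # exactly at the boundary: absent
  expect_equal(inc$Y["b", "x"], 0L)
  expect_equal(inc$Y["b", "y"], 1L)
  expect_error(call_presences(make_coverage(
    data.frame(s = "a", o = "x", f = 1.2))), "\\[0, 1\\]")
  expect_error(call_presences(make_coverage(
    data.frame(s = c("a", "a"), o = c("x", "x"), f = c(0.6, 0.7)))),
    "duplicate")
})

test_that("coverage encoding of an incidence matrix round-trips", {
  Y <- tiny_world$inc$Y[1:10, 1:5]
  cov <- expand.grid(s = rownames(Y), o = colnames(Y),
                     stringsAsFactors = FALSE)
  cov$f <- Y[cbind(cov$s, cov$o)]
  back <- call_presences(make_coverage(cov))
  expect_equal(back$Y[rownames(Y), colnames(Y)], Y)
})

test_that("filter_by_incidence keeps species at >= min_sites and is idempotent", {
  Y <- cbind(sp1 = c(rep(1, 5), rep(0, 15)),   # 5 presences: dropped at 6
             sp2 = c(rep(1, 6), rep(0, 14)),   # exactly 6: kept
             sp3 = rep(1, 20))
  inc <- incidence_matrix(Y, sprintf("s%02d", 1:20))
  f6 <- filter_by_incidence(inc, 6)
  expect_equal(f6$species_id, c("sp2", "sp3"))
  expect_equal(filter_by_incidence(f6, 6)$Y, f6$Y)
  expect_equal(ncol(filter_by_incidence(inc, 1)$Y), 3)
  expect_warning(empty <- filter_by_incidence(inc, 100), "no species")
  expect_equal(ncol(empty$Y), 0)
})

test_that("VIF reduction matches a brute-force regression oracle", {
  set.seed(31)
  X <- matrix(rnorm(50 * 5), 50, 5,
              dimnames = list(NULL, paste0("c", 1:5)))
  X[, 5] <- X[, 1] + X[, 2] + rnorm(50, sd = 0.3)  # induce collinearity
  oracle <- vapply(1:5, function(k) {
    fit <- stats::lm(X[, k] ~ X[, -k])
    1 / (1 - summary(fit)$r.squared)
  }, numeric(1))
  expect_equal(unname(sidewaysmap:::vif_values(X)), oracle,
               tolerance = 1e-10)
  # thresholding between the two largest oracle VIFs removes exactly the max
  srt <- sort(oracle, decreasing = TRUE)
  red <- reduce_covariates_vif(X, vif_threshold = mean(srt[1:2]))
  expect_equal(red$removed$covariate[1], paste0("c", which.max(oracle)))
  final_vifs <- sidewaysmap:::vif_values(red$X)
  expect_true(all(final_vifs <= mean(srt[1:2])))
})

test_that("VIF reduction handles exact duplicates and orthogonal columns", {
  set.seed(32)
  base <- qr.Q(qr(matrix(rnorm(40 * 3), 40, 3))) # orthogonal columns
  colnames(base) <- paste0("o", 1:3)
  expect_equal(reduce_covariates_vif(base, 10)$kept, colnames(base))
  dup <- cbind(base, o4 = base[, 1])
  red <- reduce_covariates_vif(dup, 10)
  expect_equal(nrow(red$removed), 1)           # exactly one of the pair goes
  expect_equal(red$removed$covariate, "o1")    # tie broken by column order
  expect_true(is.infinite(red$removed$vif))
  expect_error(reduce_covariates_vif(base[1:2, ], 10), "rows")
})

test_that("train/test split reproduces the published sizes and is sound", {
  Y <- matrix(rbinom(121 * 3, 1, 0.4), 121, 3)
  inc <- incidence_matrix(Y, sprintf("s%03d", 1:121))
  X <- matrix(rnorm(121 * 2), 121, 2)
  sp <- split_train_test(inc, X, 0.75, seed = 5)
  expect_equal(nrow(sp$train$Y$Y), 91)
  expect_equal(nrow(sp$test$Y$Y), 30)
  expect_length(intersect(sp$train$index, sp$test$index), 0)
  expect_setequal(c(sp$train$index, sp$test$index), 1:121)
  # rounding: 4 * 0.75 = 3 exactly; 2 * 0.75 = 1.5 rounds up
  inc4 <- incidence_matrix(Y[1:4, ], sprintf("s%d", 1:4))
  sp4 <- split_train_test(inc4, X[1:4, ], 0.75, seed = 1)
  expect_equal(nrow(sp4$train$Y$Y), 3)
  inc10 <- incidence_matrix(Y[1:10, ], sprintf("s%d", 1:10))
  expect_error(split_train_test(inc10, X[1:10, ], 0.999, seed = 1),
               "empty")
})

test_that("group_by_point split never separates paired traps", {
  inc <- tiny_world$inc
  sp <- split_train_test(inc, tiny_world$X, 0.75, seed = 9,
                         group_by_point = TRUE)
  shared <- intersect(sp$train$Y$point_id, sp$test$Y$point_id)
  expect_length(shared, 0)
})
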