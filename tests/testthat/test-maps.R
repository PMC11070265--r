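# tiny fitted model + landscape reused across the mapping tests
map_world <- local({
  w <- tiny_world
  hp <- jsdm_hyperparams(latent_rank = 1, epochs = 120, M = 15)
  model <- fit_jsdm(w$inc$Y, w$X, w$coords, hp, seed = 71)
  list(model = model, land = w$land)
})

test_that("species retention by predictive AUC uses an inclusive boundary", {
  a <- c(s1 = 0.70, s2 = 0.699, s3 = 0.9, s4 = NA)
  expect_equal(filter_species_by_auc(a, 0.7), c("s1", "s3"))
  expect_warning(out <- filter_species_by_auc(c(x = NA_real_), 0.7),
                 "no species")
  expect_length(out, 0)
  expect_error(filter_species_by_auc(c(1.2)), "\\[0, 1\\]")
})

test_that("raster prediction is chunk-invariant and mask-aware", {
  m <- map_world$model; land <- map_world$land
  whole <- predict_raster(m, land, chunk_size = 1e6)
  chunked <- predict_raster(m, land, chunk_size = 1)
  expect_identical(whole$probs, chunked$probs)
  # masked pixels are NoData in every species map
  land_m <- land
  land_m$mask <- matrix(TRUE, 24, 24); land_m$mask[3, 7] <- FALSE
  masked <- predict_raster(m, land_m, chunk_size = 100)
  for (p in masked$probs) expect_true(is.na(p[3, 7]))
  # schema errors name the offending band
  land_b <- land
  names(land_b$values)[2] <- "wrong"
  expect_error(predict_raster(m, land_b), "cov02")
})

test_that("a constant-covariate raster predicts the constant point value", {
  w <- tiny_world
  hp <- jsdm_hyperparams(latent_rank = 0, epochs = 80, trend_degree = 0)
  m <- fit_jsdm(w$inc$Y, w$X, coords = NULL, hyper = hp, seed = 72)
  const <- layer_stack(lapply(stats::setNames(
    as.list(w$X[5, ]), colnames(w$X)),
    function(v) matrix(v, 6, 6)))
  pm <- predict_raster(m, const)
  pt <- predict_prob(m, w$X[5, , drop = FALSE])
  for (j in seq_along(pm$probs))
    expect_true(all(abs(pm$probs[[j]] - pt[1, j]) < 1e-12))
})

test_that("richness counts species at or above the inclusive threshold", {
  P <- cbind(a = c(1, 0.5, 0.49, 0), b = c(1, 0, 0, 0))
  pm <- manual_prob_maps(P, 2, 2)
  r <- richness_map(pm, 0.5)
  expect_equal(as.vector(t(r$values)), c(2L, 1L, 0L, 0L))
  # all-ones stack: richness = n_species everywhere
  ones <- manual_prob_maps(matrix(1, 4, 3), 2, 2)
  expect_true(all(richness_map(ones)$values == 3))
  # random stack equals a brute-force per-pixel loop
  set.seed(73)
  Q <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("x", "y", "z")))
  pmq <- manual_prob_maps(Q, 4, 5)
  rq <- richness_map(pmq, 0.5)
  brute <- apply(Q, 1, function(row) sum(row >= 0.5))
  expect_equal(as.vector(t(rq$values)), as.integer(brute))
  # linearity: richness is the sum of single-species thresholded maps
  singles <- lapply(1:3, function(j)
    richness_map(manual_prob_maps(Q[, j, drop = FALSE], 4, 5), 0.5)$values)
  expect_equal(rq$values, Reduce(`+`, singles))
})

test_that("t-SNE composition separates distinct communities", {
  set.seed(74)
  A <- rep(c(0.9, 0.1, 0.9, 0.1, 0.5), each = 1)
  B <- rep(c(0.1, 0.9, 0.1, 0.9, 0.5), each = 1)
  P <- rbind(t(replicate(15, A + rnorm(5, sd = 0.01))),
             t(replicate(15, B + rnorm(5, sd = 0.01))))
  colnames(P) <- sprintf("sp%d", 1:5)
  pm <- manual_prob_maps(P, 5, 6)
  cm <- composition_map(pm, perplexity = 5, seed = 75)
  co <- cbind(as.vector(t(cm$axis1)), as.vector(t(cm$axis2)))
  within_a <- as.matrix(dist(co[1:15, ]))
  within_b <- as.matrix(dist(co[16:30, ]))
  between <- as.matrix(stats::dist(co))[1:15, 16:30]
  expect_lt(mean(c(within_a[upper.tri(within_a)],
                   within_b[upper.tri(within_b)])), mean(between))
  expect_error(composition_map(pm, perplexity = 30, seed = 1),
               "perplexity")
})

test_that("non-sampled pixels inherit their nearest sampled twin exactly", {
  set.seed(76)
  base <- matrix(runif(12 * 4), 12, 4,
                 dimnames = list(NULL, sprintf("s%d", 1:4)))
  P <- rbind(base, base)  # second half duplicates the first
  pm <- manual_prob_maps(P, 4, 6)
  # 23 of 24 pixels embedded: the one left out always has a sampled twin
  cm <- composition_map(pm, perplexity = 3, max_pixels = 23, seed = 77)
  co1 <- cbind(as.vector(t(cm$axis1)), as.vector(t(cm$axis2)))
  sampled <- cm$sampled
  rest <- setdiff(1:24, sampled)
  # every pixel has an exact twin among the sampled ones; coords must match
  for (i in rest) {
    twin <- sampled[which(apply(abs(
      P[sampled, , drop = FALSE] -
        matrix(P[i, ], length(sampled), 4, byrow = TRUE)), 1, max) < 1e-12)]
    expect_true(length(twin) >= 1)
    expect_true(any(apply(co1[twin, , drop = FALSE], 1,
                          function(z) identical(z, co1[i, ]))))
  }
  # deterministic given the seed
  cm2 <- composition_map(pm, perplexity = 3, max_pixels = 23, seed = 77)
  expect_identical(cm$axis1, cm2$axis1)
})
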