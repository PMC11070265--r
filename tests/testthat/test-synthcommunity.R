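# lag-1 spatial correlation of a layer: east and south neighbour pairs pooled
lag1_cor <- function(m) {
  east <- stats::cor(as.vector(m[, -ncol(m)]), as.vector(m[, -1]))
  south <- stats::cor(as.vector(m[-nrow(m), ]), as.vector(m[-1, ]))
  mean(c(east, south))
}

test_that("generate_landscape: standardization, autocorrelation, determinism", {
  white <- generate_landscape(c(32, 32), 3, autocorr_range = 0, seed = 1)
  smooth <- generate_landscape(c(32, 32), 3, autocorr_range = 8, seed = 1)
  for (m in white$values) {
    expect_lt(abs(mean(m)), 1e-8)
    expect_lt(abs(stats::sd(m) - 1), 1e-8)
    expect_lt(abs(lag1_cor(m)), 0.15)
  }
  for (m in smooth$values) expect_gt(lag1_cor(m), 0.5)
  again <- generate_landscape(c(32, 32), 3, autocorr_range = 8, seed = 1)
  expect_identical(smooth$values, again$values)
  expect_false(identical(
    smooth$values,
    generate_landscape(c(32, 32), 3, autocorr_range = 8, seed = 2)$values))
  expect_error(generate_landscape(c(0, 32), 3), "positive")
  expect_error(generate_landscape(c(8, 8), 0), "n_covariates")
})

test_that("generate_species: prevalence control, rank, sparsity, determinism", {
  land <- tiny_world$land
  spec <- generate_species(land, 6, latent_rank = 2, sparsity = 1 / 5,
                           seed = 7)
  expect_error(generate_species(land, 3, latent_rank = 4), "latent_rank")
  expect_equal(ncol(spec$Lambda), 2)
  # sparsity 1/n_covariates: each species uses a single covariate
  expect_true(all(lengths(lapply(spec$species, `[[`, "active")) == 1))
  tp <- true_probability(spec, land)
  prev <- vapply(tp$probs, mean, numeric(1))
  expect_true(all(prev > 0.05 & prev < 0.95))
  # intercept calibration hits the drawn target prevalence
  expect_equal(unname(prev), spec$target_prevalence, tolerance = 1e-6)
  spec0 <- generate_species(land, 6, latent_rank = 0, seed = 7)
  expect_equal(ncol(spec0$Lambda), 0)
  expect_identical(
    generate_species(land, 6, latent_rank = 2, seed = 7)$species,
    spec$species)
})

test_that("true_probability: probit closed form and latent Monte Carlo agree", {
  land <- tiny_world$land
  spec <- generate_species(land, 4, latent_rank = 2, sparsity = 0.4,
                           seed = 11)
  expect_error(true_probability(spec, generate_landscape(c(8, 8), 3, 2, 1)),
               "schema")
  tp <- true_probability(spec, land)
  for (m in tp$probs) expect_true(all(m >= 0 & m <= 1))
  # zeroed-out species: probability exactly 1/2 everywhere
  flat <- spec
  flat$Lambda <- matrix(0, 4, 2)
  for (j in 1:4) {
    flat$species[[j]]$coef <- flat$species[[j]]$coef * 0
    flat$species[[j]]$coef2 <- flat$species[[j]]$coef2 * 0
    flat$species[[j]]$intercept <- 0
  }
  expect_true(all(true_probability(flat, land)$probs[[1]] == 0.5))
  big <- flat
  big$species[[1]]$intercept <- 30
  expect_true(all(true_probability(big, land)$probs[[1]] > 1 - 1e-8))
  # marginal formula vs Monte Carlo over the latent draw, one pixel/species
  X1 <- stack_to_matrix(land)[17, , drop = FALSE]
  eta1 <- sidewaysmap:::species_eta(spec, X1)[1, 2]
  lam <- spec$Lambda[2, ]
  set.seed(42)
  draws <- stats::pnorm(eta1 + as.matrix(
    matrix(stats::rnorm(2e5), ncol = 2)) %*% lam)
  mc <- mean(draws)
  se <- stats::sd(draws) / sqrt(length(draws))
  closed <- stats::pnorm(eta1 / sqrt(1 + sum(lam^2)))
  expect_lt(abs(mc - closed), 3 * se + 1e-6)
})

test_that("sampling design pairs traps and incidence draws match truth", {
  des <- tiny_world$design
  tab <- table(des$samples$point_id)
  expect_equal(sum(tab == 2), round(0.3 * 60))
  expect_false(anyDuplicated(des$samples$sample_id) > 0)
  # paired samples share the pixel
  for (p in names(tab[tab == 2])) {
    rows <- des$samples[des$samples$point_id == p, ]
    expect_equal(rows$pixel[1], rows$pixel[2])
  }
  inc <- tiny_world$inc
  expect_identical(inc$Y,
                   simulate_incidence(tiny_world$spec, tiny_world$land,
                                      des, seed = 104)$Y)
  # a sure-thing species gives an all-ones column
  sure <- tiny_world$spec
  sure$species[[1]]$intercept <- 40
  sure$Lambda[1, ] <- 0
  Y <- simulate_incidence(sure, tiny_world$land, des, seed = 1)$Y
  expect_true(all(Y[, 1] == 1))
})

test_that("empirical incidence frequency sits within binomial error of truth", {
  land <- generate_landscape(c(50, 50), 3, autocorr_range = 3, seed = 21)
  spec <- generate_species(land, 5, latent_rank = 1, sparsity = 0.5,
                           seed = 22)
  des <- generate_design(land, 2000, paired_fraction = 0, seed = 23)
  inc <- simulate_incidence(spec, land, des, seed = 24)
  tp <- true_probability(spec, land)
  P <- sidewaysmap:::prob_maps_matrix(tp)[des$samples$pixel, ]
  for (j in 1:5) {
    expected <- mean(P[, j])
    se <- sqrt(expected * (1 - expected) / 2000)
    expect_lt(abs(mean(inc$Y[, j]) - expected), 3.5 * se)
  }
})

test_that("landscape round-trips through ASCII grids", {
  land <- tiny_world$land
  dir <- withr::local_tempdir()
  paths <- write_stack_asc(land, dir)
  back <- read_stack_asc(paths)
  expect_equal(names(back$values), names(land$values))
  expect_equal(back$values, land$values, tolerance = 1e-6)
  expect_equal(back$pixel_size, land$pixel_size)
})
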