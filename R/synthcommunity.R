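#' Generate a synthetic landscape of spatially autocorrelated covariates
#'
#' Builds a stack of standardized Gaussian-random-field layers by smoothing
#' white noise with a separable Gaussian kernel, emulating the smoothed,
#' multi-scale remote-sensing covariate products the downstream model
#' consumes. Each layer is standardized to mean 0, sd 1 over the grid.
#'
#' @param grid_shape integer (rows, cols).
#' @param n_covariates number of layers (>= 1).
#' @param autocorr_range smoothing kernel standard deviation in pixels; 0
#'   gives white noise.
#' @param seed integer seed; the result is a pure function of the arguments
#'   and the seed.
#' @param pixel_size pixel edge in metres (default 30).
#' @param layer_names optional character names (default `cov01`, ...).
#' @return a [layer_stack()].
#' @export
generate_landscape <- function(grid_shape = c(32, 32), n_covariates = 6,
                               autocorr_range = 6, seed = 1,
                               pixel_size = 30, layer_names = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2 || any(grid_shape <= 0))
    stop("grid_shape must be two positive integers")
  if (n_covariates < 1) stop("n_covariates must be >= 1")
  if (autocorr_range < 0) stop("autocorr_range must be >= 0")
  if (is.null(layer_names))
    layer_names <- sprintf("cov%02d", seq_len(n_covariates))
  stopifnot(length(layer_names) == n_covariates)
  set.seed(seed)
  Sr <- gauss_smoother(grid_shape[1], autocorr_range)
  Sc <- gauss_smoother(grid_shape[2], autocorr_range)
  vals <- lapply(seq_len(n_covariates), function(i) {
    z <- matrix(stats::rnorm(prod(grid_shape)), grid_shape[1], grid_shape[2])
    if (!is.null(Sr)) z <- Sr %*% z %*% t(Sc)
    (z - mean(z)) / stats::sd(z)
  })
  names(vals) <- layer_names
  layer_stack(vals, pixel_size = pixel_size)
}

# row-normalized banded Gaussian smoothing matrix (NULL = no smoothing)
gauss_smoother <- function(n, sigma) {
  if (sigma <= 0) return(NULL)
  S <- stats::dnorm(abs(outer(seq_len(n), seq_len(n), "-")), sd = sigma)
  S[abs(outer(seq_len(n), seq_len(n), "-")) > ceiling(3 * sigma)] <- 0
  S / rowSums(S)
}

#' Draw synthetic species response surfaces over a landscape
#'
#' Each species responds to a small subset of covariates through a linear,
#' quadratic, threshold, or multiplicative-interaction shape, with optional
#' low-rank latent loadings generating residual inter-species correlation.
#' Intercepts are calibrated by bisection so each species' marginal
#' prevalence over the landscape hits a target drawn from `prevalence_range`
#' (hence always inside [0.05, 0.95]), which makes incidence-filter behaviour
#' predictable in tests.
#'
#' @param landscape a [layer_stack()].
#' @param n_species number of species.
#' @param latent_rank number of latent factors (0 = conditionally independent
#'   species given covariates); must not exceed `n_species`.
#' @param sparsity fraction of covariates active per species, in (0, 1]; the
#'   per-species count is `max(1, round(sparsity * n_covariates))`.
#' @param seed integer seed.
#' @param shapes response shapes to draw from; `"interaction"` multiplies the
#'   first two active covariates and needs >= 2 active covariates.
#' @param prevalence_range range the per-species target prevalence is drawn
#'   from (uniform).
#' @param coef_range magnitude range for response coefficients (sign random).
#' @param loading_sd standard deviation of latent loading entries.
#' @return an object of class `species_spec` with per-species response
#'   definitions, the loading matrix `Lambda`, and the covariate schema.
#' @export
generate_species <- function(landscape, n_species = 12, latent_rank = 2,
                             sparsity = 0.25, seed = 1,
                             shapes = c("linear", "quadratic", "threshold"),
                             prevalence_range = c(0.10, 0.60),
                             coef_range = c(1.0, 2.5), loading_sd = 0.6) {
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  if (latent_rank < 0) stop("latent_rank must be >= 0")
  if (latent_rank > n_species) stop("latent_rank must not exceed n_species")
  cov_names <- names(landscape$values)
  n_cov <- length(cov_names)
  n_active <- max(1L, round(sparsity * n_cov))
  set.seed(seed)
  Lambda <- matrix(stats::rnorm(n_species * latent_rank, sd = loading_sd),
                   n_species, latent_rank)
  species <- vector("list", n_species)
  for (j in seq_len(n_species)) {
    shape <- sample(shapes, 1)
    k <- if (shape == "interaction") max(2L, n_active) else n_active
    active <- sample(cov_names, min(k, n_cov))
    coef <- stats::runif(length(active), coef_range[1], coef_range[2]) *
      sample(c(-1, 1), length(active), replace = TRUE)
    sp <- list(shape = shape, active = active, coef = coef, intercept = 0)
    if (shape == "quadratic")
      sp$coef2 <- stats::runif(length(active), 0.3, 1) *
        sample(c(-1, 1), length(active), replace = TRUE)
    if (shape == "threshold")
      sp$cut <- stats::runif(length(active), -0.5, 0.5)
    if (shape == "interaction")
      sp$coef12 <- stats::runif(1, coef_range[1], coef_range[2]) *
        sample(c(-1, 1), 1)
    species[[j]] <- sp
  }
  target_prev <- stats::runif(n_species, prevalence_range[1], prevalence_range[2])
  spec <- structure(list(species = species, Lambda = Lambda,
                         covariate_names = cov_names,
                         species_names = sprintf("sp%03d", seq_len(n_species)),
                         target_prevalence = target_prev),
                    class = "species_spec")
  # calibrate intercepts against the landscape's marginal probabilities
  X <- stack_to_matrix(landscape)
  eta0 <- species_eta(spec, X)
  s <- sqrt(1 + rowSums(Lambda^2))
  for (j in seq_len(n_species)) {
    f <- function(c0) mean(stats::pnorm((eta0[, j] + c0) / s[j])) - target_prev[j]
    spec$species[[j]]$intercept <-
      stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  }
  spec
}

# linear predictor (before intercept-free latent/noise terms) of every
# species at covariate rows X; includes the calibrated intercepts
species_eta <- function(spec, X) {
  n <- nrow(X)
  eta <- matrix(0, n, length(spec$species))
  for (j in seq_along(spec$species)) {
    sp <- spec$species[[j]]
    Xa <- X[, sp$active, drop = FALSE]
    e <- switch(sp$shape,
      linear = drop(Xa %*% sp$coef),
      quadratic = drop(Xa %*% sp$coef) + drop(Xa^2 %*% sp$coef2),
      threshold = drop((sweep(Xa, 2, sp$cut, ">") * 1) %*% sp$coef),
      interaction = drop(Xa %*% sp$coef) + sp$coef12 * Xa[, 1] * Xa[, 2],
      stop("unknown shape: ", sp$shape))
    eta[, j] <- e + sp$intercept
  }
  colnames(eta) <- spec$species_names
  eta
}

#' True marginal occurrence probabilities over a landscape
#'
#' Under the probit generative model with latent factors h ~ N(0, I_r) and
#' unit residual noise, the marginal probability is
#' `pnorm(eta / sqrt(1 + ||Lambda_j||^2))`; this closed form is the recovery
#' oracle the fitted model is compared against.
#'
#' @param spec a `species_spec` from [generate_species()].
#' @param landscape the [layer_stack()] it was generated for (same schema).
#' @return a `prob_maps` object (see [predict_raster()]): per-species
#'   probability matrices on the landscape grid.
#' @export
true_probability <- function(spec, landscape) {
  if (!identical(spec$covariate_names, names(landscape$values)))
    stop("species spec and landscape covariate schemas differ")
  X <- stack_to_matrix(landscape)
  eta <- species_eta(spec, X)
  s <- sqrt(1 + rowSums(spec$Lambda^2))
  P <- stats::pnorm(sweep(eta, 2, s, "/"))
  prob_maps_from_matrix(P, landscape)
}

prob_maps_from_matrix <- function(P, stack) {
  d <- stack_shape(stack)
  probs <- lapply(seq_len(ncol(P)), function(j)
    matrix(P[, j], d[1], d[2], byrow = TRUE))
  names(probs) <- colnames(P)
  structure(list(probs = probs, pixel_size = stack$pixel_size,
                 xll = stack$xll, yll = stack$yll, mask = stack$mask),
            class = "prob_maps")
}

#' Sampling design: points on the grid, some with paired traps
#'
#' Mirrors the field design the package emulates: trap points scattered over
#' the landscape, a fraction of them carrying two traps (paired samples at
#' the same pixel with distinct sample ids).
#'
#' @param landscape a [layer_stack()].
#' @param n_points number of sampling points (default 89).
#' @param paired_fraction fraction of points with two samples (default 32/89).
#' @param seed integer seed.
#' @return an object of class `sampling_design`: data.frame `samples`
#'   (sample_id, point_id, pixel, row, col, x, y) plus counts.
#' @export
generate_design <- function(landscape, n_points = 89,
                            paired_fraction = 32 / 89, seed = 1) {
  d <- stack_shape(landscape)
  n_pix <- prod(d)
  if (n_points > n_pix) stop("more points than pixels")
  set.seed(seed)
  centres <- pixel_centres(landscape)
  if (!is.null(landscape$mask)) {
    ok <- which(as.vector(t(landscape$mask)))
  } else ok <- seq_len(n_pix)
  pix <- sample(ok, n_points)
  n_paired <- round(paired_fraction * n_points)
  paired <- rep(c(TRUE, FALSE), c(n_paired, n_points - n_paired))
  reps <- ifelse(paired, 2L, 1L)
  idx <- rep(seq_len(n_points), reps)
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_along(idx)),
    point_id = sprintf("P%03d", idx),
    pixel = pix[idx],
    row = centres$row[pix[idx]], col = centres$col[pix[idx]],
    x = centres$x[pix[idx]], y = centres$y[pix[idx]],
    stringsAsFactors = FALSE)
  structure(list(samples = samples, n_points = n_points,
                 n_samples = nrow(samples)),
            class = "sampling_design")
}

#' Simulate a presence-absence incidence matrix at a sampling design
#'
#' Draws, for each sample, shared latent factors `h ~ N(0, I_r)` plus unit
#' probit noise, so species at one sample are correlated through `Lambda`
#' while paired samples at the same point are independent draws. Marginal
#' frequencies match [true_probability()].
#'
#' @param spec a `species_spec`.
#' @param landscape the matching [layer_stack()].
#' @param design a `sampling_design` from [generate_design()].
#' @param seed integer seed.
#' @return an `incidence_matrix` (see [incidence_matrix()]).
#' @export
simulate_incidence <- function(spec, landscape, design, seed = 1) {
  X <- stack_to_matrix(landscape)[design$samples$pixel, , drop = FALSE]
  eta <- species_eta(spec, X)
  n <- nrow(eta); S <- ncol(eta); r <- ncol(spec$Lambda)
  set.seed(seed)
  H <- matrix(stats::rnorm(n * r), n, r)
  E <- matrix(stats::rnorm(n * S), n, S)
  Z <- eta + H %*% t(spec$Lambda) + E
  Y <- (Z > 0) * 1L
  incidence_matrix(Y, sample_id = design$samples$sample_id,
                   point_id = design$samples$point_id,
                   x = design$samples$x, y = design$samples$y,
                   species_id = spec$species_names)
}

#' Presence-absence incidence matrix with sample identifiers
#'
#' The community container used throughout: a binary samples-by-species
#' matrix plus sample/point ids and optional sample coordinates.
#'
#' @param Y binary matrix (samples x species).
#' @param sample_id unique sample identifiers.
#' @param point_id sampling-point identifiers (paired traps share one).
#' @param x,y optional sample coordinates, metres.
#' @param species_id optional species identifiers (default from columns).
#' @return object of class `incidence_matrix`.
#' @export
incidence_matrix <- function(Y, sample_id, point_id = sample_id,
                             x = NULL, y = NULL, species_id = colnames(Y)) {
  Y <- as.matrix(Y)
  if (!all(Y %in% c(0, 1))) stop("incidence entries must be 0/1")
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  if (length(sample_id) != nrow(Y)) stop("sample_id length != rows of Y")
  if (is.null(species_id)) species_id <- sprintf("sp%03d", seq_len(ncol(Y)))
  dimnames(Y) <- list(sample_id, species_id)
  structure(list(Y = Y, sample_id = sample_id, point_id = point_id,
                 x = x, y = y, species_id = species_id),
            class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("incidence_matrix: %d samples x %d species, %d presences\n",
              nrow(x$Y), ncol(x$Y), sum(x$Y)))
  invisible(x)
}
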