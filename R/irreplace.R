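#' Exact Poisson-binomial probability mass function
#'
#' Distribution of the number of successes among independent Bernoulli
#' trials with probabilities `p`, by the O(n^2) dynamic-programming
#' convolution; exact up to float accumulation (the PMF sums to 1 within
#' 1e-10).
#'
#' @param p vector of success probabilities in \[0, 1\].
#' @return numeric vector of length `length(p) + 1`: P(X = 0), ..., P(X = n).
#' @export
poisson_binomial_pmf <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]")
  f <- 1
  for (pi in p) f <- c(f * (1 - pi), 0) + c(0, f * pi)
  f
}

# P(X_{-i} = target) for every i, by deconvolving pixel i out of the full
# PMF f. The recursion direction is chosen per pixel for stability
# (growth factor <= 1 both ways).
pb_leave_one_out <- function(f, p, target) {
  n <- length(p)
  stopifnot(target >= 0, target <= n - 1)
  q <- numeric(n)
  lo <- which(p <= 0.5)
  hi <- which(p > 0.5)
  if (length(lo)) {
    pl <- p[lo]
    cur <- rep(f[1], length(lo)) / (1 - pl)          # q_0
    if (target >= 1) for (k in seq_len(target))
      cur <- (f[k + 1] - pl * cur) / (1 - pl)
    q[lo] <- cur
  }
  if (length(hi)) {
    ph <- p[hi]
    cur <- rep(f[n + 1], length(hi)) / ph            # q_{n-1}
    if (target <= n - 2) for (k in (n - 1):(target + 1))
      cur <- (f[k + 1] - (1 - ph) * cur) / ph
    q[hi] <- cur
  }
  pmin(pmax(q, 0), 1)
}

#' Per-pixel alpha irreplaceability for one species
#'
#' The probability that a pixel is occupied *and* exactly pivotal for the
#' species' conservation target: `alpha_i = p_i * P(X_{-i} = t - 1)`, where
#' `X_{-i}` is Poisson-binomial over all other pixels and the integer target
#' is `t = ceiling(fraction * sum(p))` — losing pixel i then drops the
#' achievable incidence below the target. `alpha = 0` wherever `p = 0`; an
#' unreachable target (t > n) yields all-zero alpha with a warning.
#'
#' @param p per-pixel occurrence probabilities for the species.
#' @param fraction conservation-target fraction of the species' total
#'   expected incidence (default 0.5).
#' @param target optional fixed integer target t, overriding the
#'   fraction-derived one (used e.g. to study sensitivity at constant t).
#' @return numeric vector of alpha values in \[0, 1\], one per pixel, with
#'   attribute `target` (the integer t).
#' @export
alpha_irreplaceability <- function(p, fraction = 0.5, target = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]")
  n <- length(p)
  tot <- sum(p)
  if (tot == 0 && is.null(target)) return(structure(numeric(n), target = 0L))
  t_j <- if (is.null(target)) as.integer(ceiling(fraction * tot))
         else as.integer(target)
  t_j <- max(t_j, 1L)
  if (t_j > n) {
    warning("conservation target ", t_j, " exceeds pixel count ", n,
            "; alpha set to 0")
    return(structure(numeric(n), target = t_j))
  }
  f <- poisson_binomial_pmf(p)
  alpha <- p * pb_leave_one_out(f, p, t_j - 1L)
  structure(pmin(pmax(alpha, 0), 1), target = t_j)
}

#' Combine per-species alphas into per-pixel beta irreplaceability
#'
#' Under cross-species independence, the probability that losing a pixel is
#' pivotal for at least one species: `beta_i = 1 - prod_j (1 - alpha_ij)`.
#'
#' @param alpha matrix, pixels x species, values in \[0, 1\].
#' @return per-pixel beta vector in \[0, 1\].
#' @export
beta_irreplaceability <- function(alpha) {
  alpha <- as.matrix(alpha)
  if (any(alpha < 0 | alpha > 1, na.rm = TRUE))
    stop("alpha values must lie in [0, 1]")
  1 - apply(1 - alpha, 1, prod)
}

#' Site-irreplaceability raster from species probability maps
#'
#' Computes alpha irreplaceability per retained species and pixel and the
#' combined beta per pixel, over the valid (non-masked) pixels of the
#' probability maps. The Poisson-binomial machinery is O(n^2) in the pixel
#' count, so large rasters must first be pooled into planning units with
#' `block_size` (block-mean probabilities); exceeding `max_pixels` without
#' aggregation is an error instructing it.
#'
#' @param maps a `prob_maps` object ([predict_raster()] or
#'   [true_probability()]).
#' @param fraction conservation-target fraction (default 0.5).
#' @param block_size optional block edge (pixels) for aggregation into
#'   planning units; block values are written back to every member pixel.
#' @param max_pixels compute-budget guard (default 20000).
#' @return object of class `irreplaceability_result`: `beta` (matrix on the
#'   grid), `alpha` (pixels x species matrix over valid pixels), `targets`
#'   (per-species integer t), `fraction`, grid transform.
#' @export
irreplaceability_map <- function(maps, fraction = 0.5, block_size = NULL,
                                 max_pixels = 20000) {
  stopifnot(inherits(maps, "prob_maps"))
  d <- dim(maps$probs[[1]])
  work <- maps
  if (!is.null(block_size) && block_size > 1)
    work <- aggregate_prob_maps(maps, block_size)
  P <- prob_maps_matrix(work)
  valid <- if (is.null(work$mask)) rep(TRUE, nrow(P))
           else as.vector(t(work$mask))
  n <- sum(valid)
  if (n > max_pixels)
    stop(n, " pixels exceed the compute budget (", max_pixels,
         "); pass block_size to aggregate into planning units")
  Pv <- P[valid, , drop = FALSE]
  alpha <- matrix(0, n, ncol(Pv), dimnames = list(NULL, colnames(Pv)))
  targets <- integer(ncol(Pv))
  for (j in seq_len(ncol(Pv))) {
    a <- alpha_irreplaceability(Pv[, j], fraction)
    alpha[, j] <- a
    targets[j] <- attr(a, "target")
  }
  beta_v <- beta_irreplaceability(alpha)
  dw <- dim(work$probs[[1]])
  bflat <- rep(NA_real_, prod(dw))
  bflat[valid] <- beta_v
  beta <- matrix(bflat, dw[1], dw[2], byrow = TRUE)
  if (!is.null(block_size) && block_size > 1) {
    beta <- beta[rep(seq_len(dw[1]), each = block_size),
                 rep(seq_len(dw[2]), each = block_size),
                 drop = FALSE][seq_len(d[1]), seq_len(d[2]), drop = FALSE]
    if (!is.null(maps$mask)) beta[!maps$mask] <- NA
  }
  structure(list(beta = beta, alpha = alpha, targets = targets,
                 fraction = fraction, block_size = block_size,
                 pixel_size = maps$pixel_size, xll = maps$xll,
                 yll = maps$yll),
            class = "irreplaceability_result")
}

# pool a prob_maps object into block_size x block_size planning units
# (block-mean probability over valid member pixels)
aggregate_prob_maps <- function(maps, block_size) {
  d <- dim(maps$probs[[1]])
  br <- ceiling(d[1] / block_size); bc <- ceiling(d[2] / block_size)
  ridx <- (seq_len(d[1]) - 1L) %/% block_size + 1L
  cidx <- (seq_len(d[2]) - 1L) %/% block_size + 1L
  ok <- if (is.null(maps$mask)) matrix(TRUE, d[1], d[2]) else maps$mask
  cnt <- t(rowsum(t(rowsum(ok * 1, ridx)), cidx))
  pool <- function(m) {
    m0 <- m; m0[!ok] <- 0
    s <- t(rowsum(t(rowsum(m0, ridx)), cidx))
    out <- s / cnt
    out[cnt == 0] <- 0
    out
  }
  probs <- lapply(maps$probs, pool)
  structure(list(probs = probs, pixel_size = maps$pixel_size * block_size,
                 xll = maps$xll, yll = maps$yll,
                 mask = if (all(cnt > 0)) NULL else cnt > 0),
            class = "prob_maps")
}
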