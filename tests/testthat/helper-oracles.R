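# Independent oracles, kept deliberately naive so they never share code
# paths with the implementation they check.

# Poisson-binomial PMF by full 2^n enumeration
pb_enum_pmf <- function(p) {
  n <- length(p)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  pr <- apply(grid, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
  counts <- rowSums(grid)
  vapply(0:n, function(k) sum(pr[counts == k]), numeric(1))
}

# alpha irreplaceability by 2^n enumeration: probability the pixel is
# occupied and the total meets the target while it fails without the pixel
alpha_enum <- function(p, t_j) {
  n <- length(p)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  pr <- apply(grid, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
  counts <- rowSums(grid)
  vapply(seq_len(n), function(i) {
    pivotal <- grid[, i] == 1 & counts >= t_j & (counts - 1) < t_j
    sum(pr[pivotal])
  }, numeric(1))
}

# independent-probit negative log-likelihood, closed form
probit_nll_oracle <- function(eta, Y) {
  P <- stats::pnorm(eta)
  P <- pmin(pmax(P, 1e-7), 1 - 1e-7)
  -sum(ifelse(Y == 1, log(P), log(1 - P)))
}

# multivariate probit likelihood for latent rank 1 by quadrature over h
rank1_nll_quadrature <- function(eta, lambda, Y) {
  n <- nrow(eta)
  ll <- vapply(seq_len(n), function(i) {
    f <- function(h) {
      out <- stats::dnorm(h)
      for (j in seq_len(ncol(eta))) {
        pj <- stats::pnorm(eta[i, j] + lambda[j] * h)
        out <- out * (if (Y[i, j] == 1) pj else 1 - pj)
      }
      out
    }
    log(stats::integrate(f, -9, 9, rel.tol = 1e-10)$value)
  }, numeric(1))
  -sum(ll)
}

# shared small synthetic world used by several test files (cheap to build)
tiny_world <- local({
  land <- generate_landscape(c(24, 24), 5, autocorr_range = 4, seed = 101)
  spec <- generate_species(land, 8, latent_rank = 2, sparsity = 0.2,
                           seed = 102)
  design <- generate_design(land, 60, paired_fraction = 0.3, seed = 103)
  inc <- simulate_incidence(spec, land, design, seed = 104)
  X <- stack_to_matrix(land)[design$samples$pixel, , drop = FALSE]
  coords <- cbind(design$samples$x, design$samples$y)
  list(land = land, spec = spec, design = design, inc = inc,
       X = X, coords = coords)
})
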