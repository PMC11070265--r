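#' Permutation importance of each covariate for each species
#'
#' For every covariate, its column is shuffled and the drop in explanatory
#' AUC (baseline minus permuted, on the data the model was fitted to) is
#' averaged over `n_repeats` permutations, per species. The most important
#' covariate for a species is the one whose permutation degrades explanatory
#' performance the most. Trend-surface coordinates are never permuted.
#'
#' @param model a fitted [fit_jsdm()] model.
#' @param X training covariates (schema checked against the model).
#' @param Y training incidence matrix; species with single-class labels are
#'   skipped (`NA` row).
#' @param coords training coordinates if the model has a trend surface.
#' @param n_repeats permutations averaged per covariate (default 10).
#' @param seed integer seed.
#' @param shuffle set `FALSE` to use the identity permutation (drops are
#'   then exactly zero; diagnostic use).
#' @return object of class `importance_table`: `drop` (species x covariate
#'   matrix of AUC drops), `baseline` (per-species explanatory AUC),
#'   `top` (per-species argmax covariate), `counts` (species per covariate).
#' @export
permutation_importance <- function(model, X, Y, coords = NULL,
                                   n_repeats = 10, seed = 1,
                                   shuffle = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(model$covariate_names %in% colnames(X)))
    stop("unknown covariate schema: X must carry the training covariates")
  X <- X[, model$covariate_names, drop = FALSE]
  base <- species_auc(model, Y, X, coords)
  S <- ncol(Y); C <- ncol(X)
  drop <- matrix(NA_real_, S, C,
                 dimnames = list(model$species_names, colnames(X)))
  set.seed(seed)
  for (ci in seq_len(C)) {
    acc <- matrix(0, S, n_repeats)
    for (rep_i in seq_len(n_repeats)) {
      Xp <- X
      if (shuffle) Xp[, ci] <- X[sample.int(nrow(X)), ci]
      acc[, rep_i] <- species_auc(model, Y, Xp, coords)
    }
    drop[, ci] <- base - rowMeans(acc)
  }
  valid <- !is.na(base)
  top <- rep(NA_character_, S)
  top[valid] <- colnames(X)[apply(drop[valid, , drop = FALSE], 1, which.max)]
  counts <- table(factor(top, levels = colnames(X)))
  structure(list(drop = drop, baseline = base, top = top,
                 counts = as.integer(counts),
                 covariates = colnames(X)),
            class = "importance_table")
}

# partial-dependence of species probabilities on fixed covariate values:
# columns `cols` of X are set to `vals` (a row), predictions averaged
pd_point <- function(model, X, coords, cols, vals) {
  Xp <- X
  for (i in seq_along(cols)) Xp[, cols[i]] <- vals[i]
  colMeans(predict_prob(model, Xp, coords))
}

#' Pairwise interaction strength (Friedman's H-squared)
#'
#' For each covariate pair, compares the two-dimensional partial-dependence
#' function (on a quantile grid) with the sum of the one-dimensional ones;
#' H^2 is the fraction of the joint partial dependence's variance not
#' explained additively, per species, clamped to \[0, 1\]. A purely additive
#' model has H close to 0; `H(a,b) = H(b,a)` by construction. Constant
#' covariates are skipped with a warning.
#'
#' @param model a fitted [fit_jsdm()] model.
#' @param X data the partial dependence is averaged over.
#' @param coords coordinates if the model has a trend surface.
#' @param pairs two-column character matrix of covariate pairs; default all
#'   pairs.
#' @param grid_size quantile grid points per covariate (default 20).
#' @return object of class `interaction_table`: `h2` (species x pair
#'   matrix, columns named `a:b`), `pairs`, `top` (per-species strongest
#'   pair).
#' @export
interaction_importance <- function(model, X, coords = NULL, pairs = NULL,
                                   grid_size = 20) {
  X <- as.matrix(X)[, model$covariate_names, drop = FALSE]
  cn <- colnames(X)
  const <- vapply(seq_along(cn), function(i) stats::sd(X[, i]) == 0,
                  logical(1))
  if (is.null(pairs)) {
    use <- cn[!const]
    if (any(const)) warning("skipping constant covariate(s): ",
                            paste(cn[const], collapse = ", "))
    pairs <- t(utils::combn(use, 2))
  } else {
    pairs <- as.matrix(pairs)
    bad <- pairs[, 1] %in% cn[const] | pairs[, 2] %in% cn[const]
    if (any(bad)) {
      warning("skipping pair(s) with a constant covariate")
      pairs <- pairs[!bad, , drop = FALSE]
    }
  }
  if (nrow(pairs) == 0) stop("no usable covariate pairs")
  qs <- (seq_len(grid_size) - 0.5) / grid_size
  grids <- lapply(cn, function(nm)
    unique(stats::quantile(X[, nm], qs, names = FALSE, type = 7)))
  names(grids) <- cn
  S <- length(model$species_names)
  h2 <- matrix(NA_real_, S, nrow(pairs),
               dimnames = list(model$species_names,
                               paste(pairs[, 1], pairs[, 2], sep = ":")))
  pd_1d <- list()  # cache univariate PD curves: grid-points x species
  get_pd1 <- function(nm) {
    if (is.null(pd_1d[[nm]])) {
      g <- grids[[nm]]
      pd_1d[[nm]] <<- t(vapply(g, function(v)
        pd_point(model, X, coords, nm, v), numeric(S)))
    }
    pd_1d[[nm]]
  }
  for (pi in seq_len(nrow(pairs))) {
    a <- pairs[pi, 1]; b <- pairs[pi, 2]
    ga <- grids[[a]]; gb <- grids[[b]]
    PDa <- get_pd1(a); PDb <- get_pd1(b)
    cells <- expand.grid(ia = seq_along(ga), ib = seq_along(gb))
    PDab <- t(vapply(seq_len(nrow(cells)), function(ci)
      pd_point(model, X, coords, c(a, b),
               c(ga[cells$ia[ci]], gb[cells$ib[ci]])), numeric(S)))
    for (j in seq_len(S)) {
      f_ab <- PDab[, j] - mean(PDab[, j])
      f_a <- PDa[cells$ia, j] - mean(PDa[cells$ia, j])
      f_b <- PDb[cells$ib, j] - mean(PDb[cells$ib, j])
      denom <- sum(f_ab^2)
      h2[j, pi] <- if (denom < 1e-12) 0
        else min(1, max(0, sum((f_ab - f_a - f_b)^2) / denom))
    }
  }
  top <- colnames(h2)[apply(h2, 1, which.max)]
  structure(list(h2 = h2, pairs = pairs, top = top),
            class = "interaction_table")
}

#' Covariate ranking: species counts per most-important covariate
#'
#' Counts, for each covariate (and optionally each covariate pair), the
#' number of species for which it is the most important; counts sum to the
#' number of species with a valid baseline AUC.
#'
#' @param importance an `importance_table` from [permutation_importance()].
#' @param interactions optional `interaction_table`.
#' @return data.frame(kind, name, n_species) sorted by decreasing count
#'   within kind.
#' @export
summarize_importance <- function(importance, interactions = NULL) {
  if (!inherits(importance, "importance_table") ||
      length(importance$covariates) == 0)
    stop("non-empty importance_table required")
  tab <- table(factor(importance$top, levels = importance$covariates))
  out <- data.frame(kind = "main", name = names(tab),
                    n_species = as.integer(tab))
  out <- out[order(-out$n_species), ]
  if (!is.null(interactions)) {
    ti <- table(factor(interactions$top, levels = colnames(interactions$h2)))
    oi <- data.frame(kind = "interaction", name = names(ti),
                     n_species = as.integer(ti))
    out <- rbind(out, oi[order(-oi$n_species), ])
  }
  rownames(out) <- NULL
  out
}
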