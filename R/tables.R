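#' Call species presences from a barcode-coverage table
#'
#' A species is accepted as present in a sample when reads cover strictly
#' more than `min_fraction` of its reference barcode length (default 0.5);
#' the 50% boundary itself is an absence. Pairs not listed in the table are
#' absences.
#'
#' @param coverage data.frame with columns `sample_id`, `species_id`,
#'   `covered_fraction` (in \[0, 1\]); (sample, species) pairs unique.
#' @param min_fraction coverage threshold (strict inequality).
#' @return an [incidence_matrix()] over the samples and species appearing in
#'   the table, in order of first appearance.
#' @export
call_presences <- function(coverage, min_fraction = 0.5) {
  req <- c("sample_id", "species_id", "covered_fraction")
  if (!all(req %in% names(coverage)))
    stop("coverage table needs columns: ", paste(req, collapse = ", "))
  f <- coverage$covered_fraction
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("covered_fraction values must lie in [0, 1]")
  if (anyDuplicated(coverage[c("sample_id", "species_id")]))
    stop("duplicate (sample, species) pairs in coverage table")
  samples <- unique(coverage$sample_id)
  species <- unique(coverage$species_id)
  Y <- matrix(0L, length(samples), length(species),
              dimnames = list(samples, species))
  Y[cbind(match(coverage$sample_id, samples),
          match(coverage$species_id, species))] <- (f > min_fraction) * 1L
  incidence_matrix(Y, sample_id = samples, species_id = species)
}

#' Drop species observed at fewer than `min_sites` samples
#'
#' Retains species whose presence count (column sum) is at least `min_sites`
#' (default 6), preserving column order. Idempotent.
#'
#' @param inc an [incidence_matrix()].
#' @param min_sites minimum number of occupied samples (>= 1).
#' @return the filtered [incidence_matrix()].
#' @export
filter_by_incidence <- function(inc, min_sites = 6) {
  stopifnot(inherits(inc, "incidence_matrix"), min_sites >= 1)
  if (nrow(inc$Y) == 0L || ncol(inc$Y) == 0L) stop("empty incidence matrix")
  keep <- colSums(inc$Y) >= min_sites
  if (!any(keep))
    warning("no species reach the incidence threshold; returning zero species")
  out <- inc
  out$Y <- inc$Y[, keep, drop = FALSE]
  out$species_id <- inc$species_id[keep]
  out
}

#' Iterative covariate reduction by variance inflation factor
#'
#' Repeatedly removes the covariate with the largest VIF until every
#' remaining covariate's VIF is at or below `vif_threshold`. VIF_k is
#' 1 / (1 - R^2) from regressing covariate k on all other remaining
#' covariates (with intercept). Perfectly collinear columns have infinite
#' VIF; ties are broken by column order.
#'
#' @param X numeric matrix or data.frame of covariates (>= 2 columns; more
#'   rows than columns).
#' @param vif_threshold stop once all VIFs <= this (default 10).
#' @return list with `X` (reduced matrix), `kept` (names), and `removed`
#'   (data.frame: step, covariate, vif at removal).
#' @export
reduce_covariates_vif <- function(X, vif_threshold = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  if (ncol(X) < 2) stop("need at least two covariates")
  if (nrow(X) <= ncol(X))
    stop("need more rows than covariates for the VIF regressions")
  removed <- data.frame(step = integer(0), covariate = character(0),
                        vif = numeric(0))
  step <- 0L
  repeat {
    if (ncol(X) < 2) break
    v <- vif_values(X)
    if (all(v <= vif_threshold)) break
    step <- step + 1L
    drop_k <- which.max(v)  # which.max takes the first maximum: column-order ties
    removed <- rbind(removed, data.frame(
      step = step, covariate = colnames(X)[drop_k], vif = v[drop_k]))
    X <- X[, -drop_k, drop = FALSE]
  }
  list(X = X, kept = colnames(X), removed = removed)
}

vif_values <- function(X) {
  vapply(seq_len(ncol(X)), function(k) {
    y <- X[, k]
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), y)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)  # constant column: undefined, force removal
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Random train/test split of samples
#'
#' The training size is `round(n * train_fraction)` with half-counts rounded
#' up (121 samples at 75% give 91 training and 30 test samples). With
#' `group_by_point = TRUE` whole points are assigned to one side, so paired
#' traps never straddle the split.
#'
#' @param inc an [incidence_matrix()].
#' @param X covariate matrix/data.frame aligned with the samples.
#' @param train_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @param group_by_point assign by point rather than by sample.
#' @return list with elements `train` and `test`, each a list of `Y`
#'   (incidence_matrix), `X`, and `index` (row indices into the input).
#' @export
split_train_test <- function(inc, X, train_fraction = 0.75, seed = 1,
                             group_by_point = FALSE) {
  stopifnot(inherits(inc, "incidence_matrix"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  X <- as.matrix(X)
  n <- nrow(inc$Y)
  stopifnot(nrow(X) == n)
  n_train <- floor(n * train_fraction + 0.5)  # ties upward
  if (n_train == 0 || n_train == n)
    stop("split leaves an empty partition (n = ", n,
         ", train_fraction = ", train_fraction, ")")
  set.seed(seed)
  if (group_by_point) {
    pts <- unique(inc$point_id)
    ord <- sample(pts)
    take <- character(0); size <- 0
    for (p in ord) {
      if (size >= n_train) break
      take <- c(take, p); size <- size + sum(inc$point_id == p)
    }
    tr_idx <- which(inc$point_id %in% take)
  } else {
    tr_idx <- sort(sample.int(n, n_train))
  }
  te_idx <- setdiff(seq_len(n), tr_idx)
  if (length(te_idx) == 0) stop("test partition is empty")
  subset_split <- function(idx) {
    list(Y = incidence_matrix(inc$Y[idx, , drop = FALSE],
                              sample_id = inc$sample_id[idx],
                              point_id = inc$point_id[idx],
                              x = inc$x[idx], y = inc$y[idx],
                              species_id = inc$species_id),
         X = X[idx, , drop = FALSE], index = idx)
  }
  list(train = subset_split(tr_idx), test = subset_split(te_idx))
}
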