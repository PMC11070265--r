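#' Default random-search space over the model hyperparameters
#'
#' Penalty strengths are sampled log-uniformly, mixing weights uniformly,
#' the latent rank and architecture from finite choices; anything can be
#' overridden or fixed. Matches the tuning protocol: random search over
#' penalty terms and architecture, selected by cross-validated AUC.
#'
#' @param penalty_range log-uniform range for the three penalty strengths.
#' @param latent_ranks integer choices for the latent rank.
#' @param hidden_choices list of hidden-width vectors (`integer(0)` =
#'   linear).
#' @param lr fixed learning rate.
#' @param epochs fixed epoch budget per candidate fit.
#' @param M fixed Monte Carlo draws during tuning fits.
#' @param trend_degree fixed trend-surface degree.
#' @return a `search_space` list usable by [sample_candidates()].
#' @export
default_search_space <- function(penalty_range = c(1e-4, 1),
                                 latent_ranks = 0:3,
                                 hidden_choices = list(integer(0),
                                                       c(25L, 25L)),
                                 lr = 0.05, epochs = 200, M = 50,
                                 trend_degree = 2) {
  structure(list(
    env_penalty = list(type = "loguniform", min = penalty_range[1],
                       max = penalty_range[2]),
    env_mix = list(type = "uniform", min = 0, max = 1),
    trend_penalty = list(type = "loguniform", min = penalty_range[1],
                         max = penalty_range[2]),
    trend_mix = list(type = "uniform", min = 0, max = 1),
    loading_penalty = list(type = "loguniform", min = penalty_range[1],
                           max = penalty_range[2]),
    loading_mix = list(type = "uniform", min = 0, max = 1),
    latent_rank = list(type = "choice", values = as.list(latent_ranks)),
    hidden = list(type = "choice", values = hidden_choices),
    lr = list(type = "fixed", value = lr),
    epochs = list(type = "fixed", value = epochs),
    M = list(type = "fixed", value = M),
    trend_degree = list(type = "fixed", value = trend_degree)),
    class = "search_space")
}

sample_one <- function(spec) {
  switch(spec$type,
    uniform = stats::runif(1, spec$min, spec$max),
    loguniform = exp(stats::runif(1, log(spec$min), log(spec$max))),
    choice = spec$values[[sample.int(length(spec$values), 1)]],
    fixed = spec$value,
    stop("unknown space entry type: ", spec$type))
}

#' Draw random hyperparameter candidates from a search space
#'
#' @param space a [default_search_space()]-style list.
#' @param n number of candidates (>= 1).
#' @param seed integer seed; draws are reproducible.
#' @return list of [jsdm_hyperparams()].
#' @export
sample_candidates <- function(space, n = 1000, seed = 1) {
  if (length(space) == 0) stop("empty search space")
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    vals <- lapply(space, sample_one)
    do.call(jsdm_hyperparams, vals)
  })
}

# shuffled fold assignment; sizes differ by at most one
make_folds <- function(n, k, seed) {
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("fewer samples than folds")
  set.seed(seed)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(sample.int(n), rep(seq_len(k), sizes))
}

# per-species AUC of a fitted model on held-out data
species_auc <- function(model, Y, X, coords) {
  P <- predict_prob(model, X, coords)
  vapply(seq_len(ncol(Y)), function(j) auc(P[, j], Y[, j]), numeric(1))
}

#' k-fold cross-validation over hyperparameter candidates
#'
#' For each candidate: fit on k-1 folds, score the held fold by per-species
#' AUC; the candidate score is the mean over species (single-class species
#' dropped) then over folds. The best candidate is the argmax, ties broken
#' by smaller total penalty, then candidate order. Candidates whose every
#' fold fails to fit are marked failed and excluded. Test data must never be
#' passed here; tuning sees the training samples only.
#'
#' @param Y binary incidence matrix (training samples x species).
#' @param X covariate matrix aligned with `Y`.
#' @param coords optional site coordinates for the trend surface.
#' @param candidates list of [jsdm_hyperparams()].
#' @param k number of folds (default 5).
#' @param seed integer seed (folds and per-fit sub-seeds).
#' @return list of class `cv_result`: `scores` (long data.frame: candidate,
#'   fold, species, auc), `candidate_mean`, `best` (index), `best_hyper`,
#'   `folds`, `failed` (logical vector).
#' @export
kfold_cv <- function(Y, X, coords = NULL, candidates, k = 5, seed = 1) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  folds <- make_folds(n, k, seed)
  set.seed(seed + 1L)
  fit_seeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                                 length(candidates) * k),
                      length(candidates), k)
  scores <- list()
  fold_means <- matrix(NA_real_, length(candidates), k)
  for (ci in seq_along(candidates)) {
    for (fi in seq_len(k)) {
      hold <- folds[[fi]]
      fit <- tryCatch(
        fit_jsdm(Y[-hold, , drop = FALSE], X[-hold, , drop = FALSE],
                 coords = if (is.null(coords)) NULL
                          else coords[-hold, , drop = FALSE],
                 hyper = candidates[[ci]], seed = fit_seeds[ci, fi]),
        error = function(e) NULL)
      if (is.null(fit)) next
      a <- species_auc(fit, Y[hold, , drop = FALSE],
                       X[hold, , drop = FALSE],
                       if (is.null(coords)) NULL
                       else coords[hold, , drop = FALSE])
      scores[[length(scores) + 1L]] <- data.frame(
        candidate = ci, fold = fi,
        species = colnames(Y) %||% sprintf("sp%03d", seq_len(ncol(Y))),
        auc = a)
      fold_means[ci, fi] <- mean(a, na.rm = TRUE)
    }
  }
  candidate_mean <- rowMeans(fold_means, na.rm = TRUE)
  failed <- !is.finite(candidate_mean)
  if (all(failed)) stop("every candidate failed in every fold")
  pen <- vapply(candidates, total_penalty, numeric(1))
  ord <- order(-ifelse(failed, -Inf, candidate_mean), pen,
               seq_along(candidates))
  best <- ord[1]
  structure(list(
    scores = do.call(rbind, scores), candidate_mean = candidate_mean,
    best = best, best_hyper = candidates[[best]], folds = folds,
    failed = failed, k = k, seed = seed),
    class = "cv_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Refit on all training data and evaluate on the holdout
#'
#' Refits with the chosen hyperparameters on the full training set and
#' returns per-species explanatory AUC (on the training data) and
#' predictive AUC (on the held-out test data), with mean/median summaries.
#' Species absent (or omnipresent) in the test labels get `NA` predictive
#' AUC.
#'
#' @param train,test lists with elements `Y` (binary matrix), `X`, and
#'   optionally `coords` (n x 2) — the two partitions must be disjoint.
#' @param hyper the selected [jsdm_hyperparams()].
#' @param seed integer seed for the refit.
#' @return list: `model`, `explanatory`, `predictive` (named per-species
#'   AUC vectors), `summary` (data.frame of means/medians).
#' @export
final_evaluation <- function(train, test, hyper, seed = 1) {
  model <- fit_jsdm(train$Y, train$X, coords = train$coords,
                    hyper = hyper, seed = seed)
  expl <- species_auc(model, as.matrix(train$Y), train$X, train$coords)
  pred <- species_auc(model, as.matrix(test$Y), test$X, test$coords)
  names(expl) <- names(pred) <- model$species_names
  list(model = model, explanatory = expl, predictive = pred,
       summary = data.frame(
         metric = c("explanatory", "predictive"),
         mean = c(mean(expl, na.rm = TRUE), mean(pred, na.rm = TRUE)),
         median = c(stats::median(expl, na.rm = TRUE),
                    stats::median(pred, na.rm = TRUE))))
}

#' Whole-data variability protocol
#'
#' Tunes on the entire dataset by k-fold cross-validation, then re-runs a
#' k-fold cross-validation with the selected hyperparameters and returns the
#' fold-wise AUC per species — an estimate of the *variability* of
#' predictive performance. Because tuning saw all the data, the level is
#' optimistic, and the result is flagged as such; the pure holdout of
#' [final_evaluation()] is the unbiased protocol.
#'
#' @param Y,X,coords the full dataset.
#' @param candidates hyperparameter candidates for the tuning pass.
#' @param k folds (default 5).
#' @param seed integer seed.
#' @return list: `auc` (species x fold matrix), `spread` (per-species fold
#'   sd), `best_hyper`, `optimistic = TRUE`.
#' @export
variability_protocol <- function(Y, X, coords = NULL, candidates, k = 5,
                                 seed = 1) {
  Y <- as.matrix(Y)
  tune <- kfold_cv(Y, X, coords, candidates, k = k, seed = seed)
  cv <- kfold_cv(Y, X, coords, list(tune$best_hyper), k = k,
                 seed = seed + 1L)
  sc <- cv$scores
  species <- colnames(Y) %||% sprintf("sp%03d", seq_len(ncol(Y)))
  A <- matrix(NA_real_, ncol(Y), k, dimnames = list(species, NULL))
  A[cbind(match(sc$species, species), sc$fold)] <- sc$auc
  list(auc = A, spread = apply(A, 1, stats::sd, na.rm = TRUE),
       best_hyper = tune$best_hyper, optimistic = TRUE)
}
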