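#' Retain species by predictive AUC
#'
#' Keeps species whose predictive AUC reaches `min_auc` (inclusive, default
#' 0.7); missing AUCs are excluded.
#'
#' @param auc_values named per-species AUC vector (may contain `NA`).
#' @param min_auc inclusive threshold.
#' @return character vector of retained species ids (possibly empty, with a
#'   warning).
#' @export
filter_species_by_auc <- function(auc_values, min_auc = 0.7) {
  if (any(auc_values < 0 | auc_values > 1, na.rm = TRUE))
    stop("AUC values must lie in [0, 1]")
  keep <- names(auc_values)[!is.na(auc_values) & auc_values >= min_auc]
  if (length(keep) == 0)
    warning("no species reach AUC >= ", min_auc)
  keep
}

#' Predict per-species occurrence-probability rasters
#'
#' Projects the fitted model over a covariate stack, pixel by pixel (in
#' chunks; chunking is bit-identical to whole-array prediction). Band names
#' must match the training covariate schema. Masked pixels propagate as
#' NoData in every species map. Coordinates for the trend surface are the
#' pixel centres.
#'
#' @param model a fitted [fit_jsdm()] model.
#' @param stack a [layer_stack()] whose layer names match the training
#'   schema.
#' @param chunk_size pixels per prediction chunk (default 10000).
#' @param species optional subset of species ids to map.
#' @return object of class `prob_maps`: named list `probs` of probability
#'   matrices on the stack grid, plus the grid transform and mask.
#' @export
predict_raster <- function(model, stack, chunk_size = 10000,
                           species = NULL) {
  stopifnot(inherits(stack, "layer_stack"))
  missing <- setdiff(model$covariate_names, names(stack$values))
  extra <- setdiff(names(stack$values), model$covariate_names)
  if (length(missing) || length(extra))
    stop("raster band / covariate schema mismatch; missing: [",
         paste(missing, collapse = ", "), "] extra: [",
         paste(extra, collapse = ", "), "]")
  X <- stack_to_matrix(stack)[, model$covariate_names, drop = FALSE]
  valid <- attr(stack_to_matrix(stack), "valid")
  ctr <- pixel_centres(stack)
  n <- nrow(X)
  P <- matrix(NA_real_, n, length(model$species_names))
  idx <- which(valid)
  for (start in seq(1, length(idx), by = chunk_size)) {
    take <- idx[start:min(start + chunk_size - 1, length(idx))]
    P[take, ] <- predict_prob(model, X[take, , drop = FALSE],
                              coords_new = if (is.null(model$trend)) NULL
                              else cbind(ctr$x[take], ctr$y[take]))
  }
  colnames(P) <- model$species_names
  if (!is.null(species)) P <- P[, species, drop = FALSE]
  prob_maps_from_matrix_masked(P, stack)
}

prob_maps_from_matrix_masked <- function(P, stack) {
  pm <- prob_maps_from_matrix(P, stack)
  pm$mask <- stack$mask
  pm
}

#' @export
print.prob_maps <- function(x, ...) {
  d <- dim(x$probs[[1]])
  cat(sprintf("prob_maps: %d species on a %d x %d grid\n",
              length(x$probs), d[1], d[2]))
  invisible(x)
}

# pixels x species probability matrix (row-major) from prob_maps
prob_maps_matrix <- function(maps) {
  P <- vapply(maps$probs, function(m) as.vector(t(m)),
              numeric(length(maps$probs[[1]])))
  matrix(P, ncol = length(maps$probs),
         dimnames = list(NULL, names(maps$probs)))
}

#' Species-richness raster
#'
#' Per pixel, the count of species whose occurrence probability reaches
#' `threshold` (inclusive, default 0.5 — a pixel at exactly 0.5 counts as
#' predicted present). NoData pixels stay NoData.
#'
#' @param maps a `prob_maps` object.
#' @param threshold inclusive presence threshold.
#' @return list of class `richness_map`: `values` (integer matrix),
#'   `threshold`, grid transform.
#' @export
richness_map <- function(maps, threshold = 0.5) {
  stopifnot(inherits(maps, "prob_maps"))
  R <- Reduce(`+`, lapply(maps$probs, function(m) (m >= threshold) * 1L))
  structure(list(values = R, threshold = threshold,
                 pixel_size = maps$pixel_size, xll = maps$xll,
                 yll = maps$yll),
            class = "richness_map")
}

#' Community-composition ordination of the landscape (t-SNE)
#'
#' Embeds pixels into two t-SNE axes using the per-species occurrence
#' probabilities as features, so pixels with similar predicted communities
#' receive similar coordinates. Large landscapes are embedded on a random
#' subsample of pixels and the remaining pixels are assigned the
#' coordinates of their nearest sampled neighbour in species space. Axes
#' are sign/rotation-arbitrary; only distance relations are meaningful.
#'
#' @param maps a `prob_maps` object (>= 3 non-masked pixels).
#' @param perplexity t-SNE perplexity; must be < number of embedded pixels.
#' @param max_pixels subsample size (default 10000).
#' @param seed integer seed (subsample and embedding).
#' @return list of class `composition_map`: `axis1`, `axis2` (matrices on
#'   the grid), `sampled` (pixel indices actually embedded).
#' @export
composition_map <- function(maps, perplexity = 30, max_pixels = 10000,
                            seed = 1) {
  stopifnot(inherits(maps, "prob_maps"))
  P <- prob_maps_matrix(maps)
  valid <- if (is.null(maps$mask)) rep(TRUE, nrow(P))
           else as.vector(t(maps$mask))
  idx <- which(valid)
  if (length(idx) < 3) stop("need at least 3 non-masked pixels")
  set.seed(seed)
  samp <- if (length(idx) > max_pixels) sort(sample(idx, max_pixels)) else idx
  if (perplexity >= length(samp))
    stop("perplexity (", perplexity, ") must be < embedded pixels (",
         length(samp), ")")
  perp <- min(perplexity, floor((length(samp) - 1) / 3))
  if (perp < 1) stop("too few pixels for any perplexity")
  emb <- Rtsne::Rtsne(P[samp, , drop = FALSE], dims = 2,
                      perplexity = perp, check_duplicates = FALSE,
                      pca = FALSE, max_iter = 500)$Y
  co <- matrix(NA_real_, nrow(P), 2)
  co[samp, ] <- emb
  rest <- setdiff(idx, samp)
  if (length(rest)) {
    nn <- FNN::get.knnx(P[samp, , drop = FALSE],
                        P[rest, , drop = FALSE], k = 1)$nn.index[, 1]
    co[rest, ] <- emb[nn, , drop = FALSE]
  }
  d <- dim(maps$probs[[1]])
  structure(list(
    axis1 = matrix(co[, 1], d[1], d[2], byrow = TRUE),
    axis2 = matrix(co[, 2], d[1], d[2], byrow = TRUE),
    sampled = samp, perplexity = perp,
    pixel_size = maps$pixel_size, xll = maps$xll, yll = maps$yll),
    class = "composition_map")
}
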