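#' Default pipeline configuration
#'
#' A fully populated configuration for [run_pipeline()], sized as the demo
#' world: a 32 x 32 landscape with 6 covariates, 12 species, the field
#' campaign's sampling structure (89 points, a third with paired traps,
#' hence 121 samples split 91/30), 20 tuning candidates under fivefold
#' cross-validation, and every downstream product. Any entry can be
#' overridden via `overrides` (recursively merged) or a YAML file with the
#' same structure.
#'
#' @param overrides named list merged over the defaults.
#' @return nested configuration list.
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1,
    out_dir = NULL,
    simulate = list(
      grid = c(32, 32), n_covariates = 6, autocorr_range = 6,
      pixel_size = 30, n_species = 12, latent_rank = 2, sparsity = 0.25,
      n_points = 89, paired_fraction = 32 / 89),
    prep = list(min_sites = 6, vif_threshold = 10, train_fraction = 0.75,
                group_by_point = FALSE),
    tune = list(n_candidates = 20, k = 5, epochs = 150, M = 25,
                penalty_range = c(1e-4, 1), latent_ranks = 0:2,
                hidden_choices = list(integer(0), c(25L, 25L))),
    importance = list(n_repeats = 5, interactions = TRUE, grid_size = 8,
                      top_covariates = 4),
    map = list(min_auc = 0.7, richness_threshold = 0.5, perplexity = 30,
               max_pixels = 5000, chunk_size = 5000),
    irreplace = list(fraction = 0.5, block_size = NULL, max_pixels = 20000))
  modifyList(cfg, overrides)
}

read_config <- function(path)
  default_config(yaml::read_yaml(path))

#' Validate agreement between community tables and a covariate stack
#'
#' Schema and sanity checks before modelling: the site covariate table and
#' the raster bands must agree, incidence must be binary with unique sample
#' ids, and sample coordinates must fall inside the raster extent. Problems
#' are reported, not thrown.
#'
#' @param inc an [incidence_matrix()].
#' @param X site covariate matrix/data.frame.
#' @param stack optional [layer_stack()].
#' @return data.frame(severity, message); zero rows when everything agrees.
#' @export
validate_inputs <- function(inc, X, stack = NULL) {
  rep_ <- data.frame(severity = character(0), message = character(0))
  add <- function(sev, msg) rbind(rep_, data.frame(severity = sev,
                                                   message = msg))
  if (!all(inc$Y %in% c(0, 1)))
    rep_ <- add("error", paste0("non-binary incidence value(s): ",
                                paste(unique(inc$Y[!(inc$Y %in% c(0, 1))]),
                                      collapse = ", ")))
  if (anyDuplicated(inc$sample_id))
    rep_ <- add("error", "duplicate sample ids")
  X <- as.matrix(X)
  if (nrow(X) != nrow(inc$Y))
    rep_ <- add("error", "covariate table and incidence row counts differ")
  if (!is.null(stack)) {
    miss <- setdiff(colnames(X), names(stack$values))
    for (m in miss)
      rep_ <- add("error", paste0("raster band missing for covariate: ", m))
    extra <- setdiff(names(stack$values), colnames(X))
    for (m in extra)
      rep_ <- add("warning", paste0("raster band not in site table: ", m))
    if (!is.null(inc$x)) {
      d <- dim(stack$values[[1]])
      xmax <- stack$xll + ncol(stack$values[[1]]) * stack$pixel_size
      ymax <- stack$yll + d[1] * stack$pixel_size
      out <- inc$x < stack$xll | inc$x > xmax |
        inc$y < stack$yll | inc$y > ymax
      if (any(out))
        rep_ <- add("error", paste0(sum(out),
                                    " sample(s) outside the raster extent"))
    }
  }
  rep_
}

write_csv_ <- function(x, path) utils::write.csv(x, path, row.names = FALSE)

#' Run the full sideways-mapping pipeline
#'
#' Executes simulate -> prep -> tune -> fit/evaluate -> importance -> map ->
#' irreplace on a synthetic world, writing every artifact (tables as CSV,
#' rasters as ESRI ASCII grids, the fitted model as JSON, configuration and
#' best hyperparameters as YAML) plus a provenance manifest with input
#' hashes. The run is a pure function of the configuration, so a rerun
#' reproduces identical file hashes.
#'
#' @param config a configuration list ([default_config()]) or the path of a
#'   YAML file of overrides.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with the main in-memory artifacts and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  out <- out_dir %||% config$out_dir
  if (is.null(out)) stop("an output directory is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed

  # -- simulate --------------------------------------------------------------
  sim <- config$simulate
  say("[simulate] %dx%d grid, %d covariates, %d species",
      sim$grid[1], sim$grid[2], sim$n_covariates, sim$n_species)
  land <- generate_landscape(sim$grid, sim$n_covariates,
                             sim$autocorr_range, seed = seed,
                             pixel_size = sim$pixel_size)
  spec <- generate_species(land, sim$n_species, sim$latent_rank,
                           sim$sparsity, seed = seed + 1)
  design <- generate_design(land, sim$n_points, sim$paired_fraction,
                            seed = seed + 2)
  inc <- simulate_incidence(spec, land, design, seed = seed + 3)
  write_stack_asc(land, file.path(out, "covariates"))
  inc_df <- data.frame(sample_id = inc$sample_id, point_id = inc$point_id,
                       x = inc$x, y = inc$y, inc$Y, check.names = FALSE)
  write_csv_(inc_df, file.path(out, "incidence.csv"))

  # -- prep ------------------------------------------------------------------
  prep <- config$prep
  inc_f <- filter_by_incidence(inc, prep$min_sites)
  say("[prep] %d/%d species pass the incidence filter",
      ncol(inc_f$Y), ncol(inc$Y))
  X_sites <- stack_to_matrix(land)[design$samples$pixel, , drop = FALSE]
  vif <- reduce_covariates_vif(X_sites, prep$vif_threshold)
  say("[prep] %d/%d covariates retained after VIF reduction",
      length(vif$kept), ncol(X_sites))
  write_csv_(vif$removed, file.path(out, "vif_removed.csv"))
  split <- split_train_test(inc_f, vif$X, prep$train_fraction,
                            seed = seed + 4,
                            group_by_point = isTRUE(prep$group_by_point))
  tr <- list(Y = split$train$Y$Y, X = split$train$X,
             coords = cbind(split$train$Y$x, split$train$Y$y))
  te <- list(Y = split$test$Y$Y, X = split$test$X,
             coords = cbind(split$test$Y$x, split$test$Y$y))

  # -- tune ------------------------------------------------------------------
  tu <- config$tune
  space <- default_search_space(
    penalty_range = tu$penalty_range, latent_ranks = tu$latent_ranks,
    hidden_choices = tu$hidden_choices, epochs = tu$epochs, M = tu$M)
  cands <- sample_candidates(space, tu$n_candidates, seed = seed + 5)
  say("[tune] %d candidates, %d-fold CV on %d training samples",
      length(cands), tu$k, nrow(tr$Y))
  cv <- kfold_cv(tr$Y, tr$X, tr$coords, cands, k = tu$k, seed = seed + 6)
  write_csv_(cv$scores, file.path(out, "cv_results.csv"))
  yaml::write_yaml(unclass(cv$best_hyper),
                   file.path(out, "best_hyperparams.yaml"))

  # -- fit + evaluate --------------------------------------------------------
  ev <- final_evaluation(tr, te, cv$best_hyper, seed = seed + 7)
  say("[evaluate] mean explanatory AUC %.3f, mean predictive AUC %.3f",
      ev$summary$mean[1], ev$summary$mean[2])
  save_jsdm(ev$model, file.path(out, "model.json"))
  write_csv_(data.frame(species = names(ev$explanatory),
                        explanatory_auc = ev$explanatory,
                        predictive_auc = ev$predictive),
             file.path(out, "auc.csv"))
  write_csv_(data.frame(epoch = seq_along(ev$model$loss_trace),
                        loss = ev$model$loss_trace),
             file.path(out, "training_log.csv"))

  # -- importance ------------------------------------------------------------
  imp_cfg <- config$importance
  imp <- permutation_importance(ev$model, tr$X, tr$Y, tr$coords,
                                n_repeats = imp_cfg$n_repeats,
                                seed = seed + 8)
  write_csv_(data.frame(species = rep(rownames(imp$drop),
                                      ncol(imp$drop)),
                        covariate = rep(colnames(imp$drop),
                                        each = nrow(imp$drop)),
                        auc_drop = as.vector(imp$drop)),
             file.path(out, "importance.csv"))
  inter <- NULL
  if (isTRUE(imp_cfg$interactions)) {
    top_cov <- names(sort(colSums(imp$drop, na.rm = TRUE),
                          decreasing = TRUE))
    top_cov <- utils::head(top_cov, imp_cfg$top_covariates)
    inter <- interaction_importance(ev$model, tr$X, tr$coords,
                                    pairs = t(utils::combn(top_cov, 2)),
                                    grid_size = imp_cfg$grid_size)
    write_csv_(data.frame(species = rep(rownames(inter$h2),
                                        ncol(inter$h2)),
                          pair = rep(colnames(inter$h2),
                                     each = nrow(inter$h2)),
                          h2 = as.vector(inter$h2)),
               file.path(out, "interactions.csv"))
  }
  write_csv_(summarize_importance(imp, inter),
             file.path(out, "importance_summary.csv"))

  # -- map -------------------------------------------------------------------
  mp <- config$map
  retained <- filter_species_by_auc(ev$predictive, mp$min_auc)
  say("[map] %d species with predictive AUC >= %g", length(retained),
      mp$min_auc)
  maps_all <- predict_raster(ev$model, land, chunk_size = mp$chunk_size)
  maps <- maps_all
  if (length(retained) > 0) maps$probs <- maps_all$probs[retained]
  dir.create(file.path(out, "species_maps"), showWarnings = FALSE)
  for (sp in names(maps$probs))
    write_ascii_grid(maps$probs[[sp]],
                     file.path(out, "species_maps", paste0(sp, ".asc")),
                     maps$xll, maps$yll, maps$pixel_size)
  rich <- richness_map(maps, mp$richness_threshold)
  write_ascii_grid(rich$values, file.path(out, "richness.asc"),
                   rich$xll, rich$yll, rich$pixel_size)
  comp <- composition_map(maps, perplexity = mp$perplexity,
                          max_pixels = mp$max_pixels, seed = seed + 9)
  write_ascii_grid(comp$axis1, file.path(out, "tsne_1.asc"),
                   comp$xll, comp$yll, comp$pixel_size)
  write_ascii_grid(comp$axis2, file.path(out, "tsne_2.asc"),
                   comp$xll, comp$yll, comp$pixel_size)

  # -- irreplace -------------------------------------------------------------
  ir_cfg <- config$irreplace
  ir <- irreplaceability_map(maps, fraction = ir_cfg$fraction,
                             block_size = ir_cfg$block_size,
                             max_pixels = ir_cfg$max_pixels)
  write_ascii_grid(ir$beta, file.path(out, "irreplaceability.asc"),
                   ir$xll, ir$yll, ir$pixel_size)

  yaml::write_yaml(config, file.path(out, "config.yaml"))
  files <- sort(list.files(out, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package = "sidewaysmap",
    version = as.character(utils::packageVersion("sidewaysmap")),
    seed = seed,
    retained_species = retained,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out, files))), files)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out, "manifest.json"))
  say("[done] %d files in %s", length(files) + 1, out)
  invisible(list(landscape = land, species = spec, incidence = inc,
                 split = split, cv = cv, evaluation = ev,
                 importance = imp, interactions = inter, maps = maps,
                 richness = rich, composition = comp,
                 irreplaceability = ir, manifest = manifest,
                 retained = retained))
}
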