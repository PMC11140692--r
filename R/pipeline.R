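#' Pipeline run configuration
#'
#' Bundles the stage toggles, stage parameters and per-stage seeds for a
#' full synthetic-scene run. Every stochastic stage has an explicit seed
#' recorded in the run manifest.
#'
#' @param scene a [scene_config()].
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "features", "classify", "assess", "expansion",
#'   "maxent", "tiers")`. Later stages require their upstream stages.
#' @param m harmonics for feature extraction.
#' @param n_trees,n_per_class classifier settings.
#' @param n_presences presences drawn for the distribution model.
#' @param sdm_weights,sdm_intercept truth law of the suitability surface.
#' @param n_replicates Maxent evaluation replicates.
#' @param seeds named list of per-stage seeds (`train`, `valid`, `env`,
#'   `presence`, `maxent`).
#' @param out_dir optional output directory; when set, stage outputs are
#'   written (ASCII grids, CSV, JSON) and checksummed in the manifest.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(scene = scene_config(),
                            stages = c("simulate", "features", "classify",
                                       "assess", "expansion", "maxent",
                                       "tiers"),
                            m = 2, n_trees = 500, n_per_class = 100,
                            n_presences = 200, sdm_weights = c(3, 0),
                            sdm_intercept = -4, n_replicates = 5,
                            seeds = list(train = 11, valid = 12, env = 13,
                                         presence = 14, maxent = 15),
                            out_dir = NULL) {
  known <- c("simulate", "features", "classify", "assess", "expansion",
             "maxent", "tiers")
  stages <- match.arg(stages, known, several.ok = TRUE)
  deps <- list(features = "simulate", classify = "features",
               assess = "classify", expansion = "classify",
               maxent = "simulate", tiers = c("maxent", "classify"))
  for (s in stages) {
    missing <- setdiff(deps[[s]], stages)
    if (length(missing)) {
      stop(sprintf("stage '%s' requires stage(s): %s", s,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(scene = scene, stages = stages, m = m, n_trees = n_trees,
                 n_per_class = n_per_class, n_presences = n_presences,
                 sdm_weights = sdm_weights, sdm_intercept = sdm_intercept,
                 n_replicates = n_replicates, seeds = seeds,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> indices/harmonics/features -> classify -> assess
#' -> expansion -> maxent -> tiers on a synthetic scene, skipping disabled
#' stages, and returns a manifest (seeds, stage summaries, output
#' checksums). Stage outputs are pure functions of the configuration and
#' seeds: re-running an identical configuration reproduces identical
#' checksums.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_run`: `manifest` plus the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list()
  manifest <- list(package = "cordgrass",
                   version = as.character(utils::packageVersion("cordgrass")),
                   seeds = config$seeds,
                   scene_seed = config$scene$seed,
                   stages = list())
  on <- function(s) s %in% config$stages
  mark_skipped <- function(s) manifest$stages[[s]] <<- list(status = "skipped")

  if (on("simulate")) {
    res$scene <- generate_scene(config$scene)
    manifest$stages$simulate <- list(
      status = "done", n_dates = length(res$scene$dates),
      valid_fraction = mean(res$scene$valid))
  } else mark_skipped("simulate")

  if (on("features")) {
    res$features <- scene_features(res$scene, m = config$m)
    manifest$stages$features <- list(
      status = "done", n_ok = sum(attr(res$features, "ok")),
      n_pixels = nrow(res$features))
  } else mark_skipped("features")

  if (on("classify")) {
    train <- make_training_set(res$features, res$scene$class_raster,
                               n_per_class = config$n_per_class,
                               seed = config$seeds$train)
    res$model <- train_classifier(train, n_trees = config$n_trees,
                                  seed = config$seeds$train)
    res$map <- predict_map(res$model, res$features, res$scene$class_raster)
    manifest$stages$classify <- list(
      status = "done", oob_error = oob_error(res$model),
      spartina_pixels = sum(raster_values(res$map$binary) == 1, na.rm = TRUE))
  } else mark_skipped("classify")

  if (on("assess")) {
    val <- stratified_validation_sample(res$map, seed = config$seeds$valid)
    res$confusion <- map_accuracy(res$map, res$scene$class_raster,
                                  cells = val$cell)
    manifest$stages$assess <- list(
      status = "done", oa = res$confusion$oa,
      kappa = round(res$confusion$kappa, 4))
  } else mark_skipped("assess")

  if (on("expansion")) {
    res$patches <- extract_patches(res$map$binary)
    res$centroid <- weighted_centroid(res$patches,
                                      epoch = format(config$scene$start_date, "%Y"))
    manifest$stages$expansion <- list(
      status = "done", n_patches = nrow(res$patches),
      total_area_hm2 = res$centroid$total_area_hm2,
      centroid = c(res$centroid$x, res$centroid$y))
  } else mark_skipped("expansion")

  if (on("maxent")) {
    env <- generate_env_layers(config$scene,
                               n_continuous = length(config$sdm_weights),
                               suitability_weights = config$sdm_weights,
                               intercept = config$sdm_intercept,
                               seed = config$seeds$env)
    pres <- sample_presences(env$suitability, config$n_presences,
                             seed = config$seeds$presence)
    occ <- dedupe_occurrences(pres, env$suitability)
    env$stack <- prune_variables(env$stack)
    res$sdm <- evaluate_replicates(occ, env$stack,
                                   n_replicates = config$n_replicates,
                                   seed = config$seeds$maxent)
    res$env <- env
    res$occ <- occ
    manifest$stages$maxent <- list(
      status = "done", n_occurrences = nrow(occ),
      mean_auc = res$sdm$mean_auc)
  } else mark_skipped("maxent")

  if (on("tiers")) {
    full <- fit_maxent(res$occ, res$env$stack, seed = config$seeds$maxent)
    suit <- maxent_suitability(full, res$env$stack)
    pres_scores <- logistic_output(full, cells = res$occ$cell)
    bg_scores <- logistic_output(full)
    thr <- threshold_max_ss(pres_scores, bg_scores)
    # resample scene masks onto the SDM grid is unnecessary here: the env
    # grid matches the scene grid by construction
    sa_mask <- res$map$binary
    mg_mask <- raster_like(res$scene$class_raster,
                           as.numeric(as.integer(res$scene$class_raster$values) == 2L))
    tf_mask <- raster_like(res$scene$class_raster,
                           as.numeric(as.integer(res$scene$class_raster$values) == 3L))
    res$tiers <- classify_tiers(suit, thr, sa_mask, mg_mask, tf_mask)
    res$suitability <- suit
    manifest$stages$tiers <- list(
      status = "done", threshold = thr,
      table = res$tiers$table)
  } else mark_skipped("tiers")

  if (!is.null(config$out_dir)) {
    manifest$outputs <- write_pipeline_outputs(res, config$out_dir)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res$manifest <- manifest
  class(res) <- "pipeline_run"
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put_grid <- function(r, nm) {
    p <- file.path(out_dir, nm)
    write_ascii_grid(r, p)
    paths <<- c(paths, p)
  }
  put_csv <- function(df, nm) {
    p <- file.path(out_dir, nm)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(res$scene)) {
    put_grid(res$scene$class_raster, "truth_classes.asc")
    put_csv(data.frame(date = format(res$scene$dates),
                       fractional_year = res$scene$times),
            "date_manifest.csv")
  }
  if (!is.null(res$map)) {
    put_grid(res$map$class_raster, "classified.asc")
    put_grid(res$map$binary, "spartina_binary.asc")
  }
  if (!is.null(res$confusion)) {
    p <- file.path(out_dir, "confusion.json")
    jsonlite::write_json(
      list(oa = res$confusion$oa, kappa = res$confusion$kappa,
           pa = as.list(res$confusion$pa), ua = as.list(res$confusion$ua),
           counts = as.data.frame(res$confusion$table)),
      p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  if (!is.null(res$patches)) {
    put_csv(as.data.frame(res$patches), "patches.csv")
    put_csv(data.frame(epoch = res$centroid$epoch, x = res$centroid$x,
                       y = res$centroid$y,
                       total_area_hm2 = res$centroid$total_area_hm2),
            "centroid.csv")
  }
  if (!is.null(res$suitability)) put_grid(res$suitability, "suitability.asc")
  if (!is.null(res$tiers)) {
    put_grid(res$tiers$tiers, "tiers.asc")
    put_csv(res$tiers$table, "tier_table.csv")
  }
  sums <- tools::md5sum(paths)
  stats::setNames(as.list(unname(sums)), basename(paths))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  for (s in names(x$manifest$stages)) {
    st <- x$manifest$stages[[s]]
    cat(sprintf("  %-10s %s\n", s, st$status))
  }
  invisible(x)
}
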