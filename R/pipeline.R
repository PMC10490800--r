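#' Default pipeline configuration
#'
#' Declarative description of a full run: simulate (or ingest) -> trim ->
#' MCCV outlier rejection -> preprocess -> wavelength selection -> split ->
#' train -> evaluate -> map. The defaults express the reference workflow:
#' second-derivative preprocessing, CARS selection, PLSR, random 75/25
#' split.
#'
#' @param n_samples simulated sample count
#' @param seed master seed; stage seeds are derived from it
#' @param trim trim interval in nm
#' @param mccv list: `n_iterations`, `train_fraction`, `z_threshold`
#' @param preprocess preprocessing method (see [preprocess_fit()])
#' @param selector `"cars"`, `"spa"` or `"none"`
#' @param model `"plsr"` or `"rfr"`
#' @param split list: `method`, `test_fraction`
#' @param scene list: `shape`, `n_pellets` for the mapping stage, or
#'   `NULL` to skip mapping
#' @param sim a [sim_config] for the simulated input
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(n_samples = 144L, seed = 20230901L,
                            trim = c(960, 2489),
                            mccv = list(n_iterations = 1000L,
                                        train_fraction = 0.75,
                                        z_threshold = 3),
                            preprocess = "SD",
                            selector = c("cars", "spa", "none"),
                            model = c("plsr", "rfr"),
                            split = list(method = "random",
                                         test_fraction = 0.25),
                            scene = list(shape = c(120L, 160L),
                                         n_pellets = 6L),
                            sim = NULL) {
  selector <- match.arg(selector)
  model <- match.arg(model)
  if (is.null(sim)) sim <- sim_config(n_samples = n_samples, seed = seed)
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 trim = trim, mccv = mccv, preprocess = preprocess,
                 selector = selector, model = model, split = split,
                 scene = scene, sim = sim),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; recognized keys mirror the arguments of
#'   [pipeline_config()]
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- cfg[intersect(names(cfg),
                        names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(structure(class = c("pipeline_stage_error", "error", "condition"),
                   list(message = sprintf("[stage:%s] %s", name,
                                          conditionMessage(e)),
                        call = NULL, stage = name))))
}

#' Run the full moisture-calibration pipeline
#'
#' Executes the stages in their canonical order on simulated input and
#' writes every intermediate artifact plus a manifest (config, seeds, file
#' hashes) to `out_dir`. Identical config and seed give identical outputs.
#'
#' Stage order: simulate references and spectra -> trim edge bands -> MCCV
#' outlier rejection on the trimmed raw spectra -> preprocessing ->
#' wavelength selection on the preprocessed post-rejection population ->
#' train/test split -> model training -> evaluation -> pixel-wise map of a
#' simulated scene. Selection precedes the split, as in the reference
#' chemometric workflow; the held-out metrics therefore validate the
#' model, not the wavelength selection (see the methods vignette).
#'
#' @param config a `pipeline_config` (or path understood by
#'   [read_pipeline_config()])
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output
#' @param verbose log stage progress to stderr
#' @return list of class `pipeline_result`: `evaluation`
#'   (an [evaluation_report]), `selection`, `outliers`, `model`, `map`,
#'   `config`, plus artifact `paths` when `out_dir` is given
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed

  log("stage simulate")
  refs <- stage("simulate", generate_reference_values(
    config$n_samples, config$sim$moisture_range, config$sim$other_fraction,
    seed = seed))
  gen <- stage("simulate", generate_spectra(refs, default_grid(), config$sim))
  spectra <- gen$spectra

  log("stage trim")
  trimmed <- stage("trim", trim_bands(spectra, config$trim[1], config$trim[2]))

  log("stage outliers")
  report <- stage("outliers", mccv_residuals(
    trimmed, refs,
    train_fraction = config$mccv$train_fraction,
    n_iterations = config$mccv$n_iterations,
    seed = seed + 1L))
  flagged <- stage("outliers", flag_outliers(report,
                                             z_threshold = config$mccv$z_threshold))
  keep <- !(trimmed$sample_ids %in% flagged)
  clean <- spectra_set(trimmed$matrix[keep, , drop = FALSE],
                       trimmed$wavelengths, trimmed$sample_ids[keep])
  refs_clean <- reference_table(refs$sample_id[keep], refs$moisture[keep])

  log("stage preprocess (%s)", config$preprocess)
  y_clean <- align_refs(clean, refs_clean)
  pp <- stage("preprocess", preprocess_fit(config$preprocess, clean))
  clean_pp <- stage("preprocess", preprocess_apply(pp, clean))

  log("stage select (%s)", config$selector)
  selection <- stage("select", switch(config$selector,
    cars = cars_select(clean_pp, y_clean, seed = seed + 3L),
    spa = spa_select(clean_pp, y_clean, Nmin = 5L, Nmax = 40L,
                     seed = seed + 3L),
    none = NULL))
  sel_idx <- if (is.null(selection)) seq_len(ncol(clean_pp$matrix))
             else selection$selected_indices

  log("stage split")
  sp <- stage("split", split_samples(clean_pp,
                                     test_fraction = config$split$test_fraction,
                                     method = config$split$method,
                                     seed = seed + 2L))
  train_pp <- clean_pp; test_pp <- clean_pp
  train_pp$matrix <- clean_pp$matrix[sp$train, , drop = FALSE]
  train_pp$sample_ids <- clean_pp$sample_ids[sp$train]
  test_pp$matrix <- clean_pp$matrix[sp$test, , drop = FALSE]
  test_pp$sample_ids <- clean_pp$sample_ids[sp$test]
  y_train <- y_clean[sp$train]
  y_test <- y_clean[sp$test]
  Xtr <- train_pp$matrix[, sel_idx, drop = FALSE]
  Xte <- test_pp$matrix[, sel_idx, drop = FALSE]

  log("stage train (%s)", config$model)
  if (config$model == "plsr") {
    ncsel <- stage("train", select_nc(Xtr, y_train, max_nc = 15L,
                                      folds = 10L, seed = seed + 4L))
    model <- stage("train", fit_plsr(Xtr, y_train, ncsel$nc))
    rmsecv <- ncsel$rmsecv[ncsel$nc]
  } else {
    model <- stage("train", fit_rfr(Xtr, y_train, seed = seed + 4L))
    rmsecv <- stage("train", {
      fold_id <- cv_folds(length(y_train), 10L, seed + 4L)
      sse <- 0
      for (f in sort(unique(fold_id))) {
        tr <- fold_id != f
        fm <- fit_rfr(Xtr[tr, , drop = FALSE], y_train[tr], seed = seed + 4L)
        sse <- sse + sum((y_train[!tr] -
                            predict(fm, Xtr[!tr, , drop = FALSE]))^2)
      }
      sqrt(sse / length(y_train))
    })
  }

  log("stage evaluate")
  evaluation <- stage("evaluate", evaluation_report(
    y_train, predict(model, Xtr),
    y_test, predict(model, Xte),
    rmsecv = rmsecv))

  map <- NULL; scene <- NULL
  if (!is.null(config$scene)) {
    log("stage map")
    np <- min(config$scene$n_pellets, nrow(refs_clean))
    scene_refs <- reference_table(refs_clean$sample_id[seq_len(np)],
                                  refs_clean$moisture[seq_len(np)])
    scene <- stage("map", generate_scene(scene_refs, default_grid(),
                                         config$sim,
                                         shape = config$scene$shape))
    refl <- stage("map", correct_reflectance(scene$raw, scene$dark,
                                             scene$white))
    map <- stage("map", predict_map(refl, scene$truth$sample_mask, model,
                                    chain = list(pp), selection = selection,
                                    trim = config$trim))
  }

  result <- structure(list(evaluation = evaluation, selection = selection,
                           outliers = list(report = report, flagged = flagged),
                           model = model, map = map, scene = scene,
                           n_components = if (config$model == "plsr") model$nc
                                          else NA_integer_,
                           config = config),
                      class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    paths$spectra <- file.path(out_dir, "spectra.csv")
    write_spectra_csv(trimmed, paths$spectra)
    paths$refs <- file.path(out_dir, "references.csv")
    utils::write.csv(refs, paths$refs, row.names = FALSE)
    paths$outliers <- file.path(out_dir, "outlier_report.csv")
    rep_df <- as.data.frame(report)
    rep_df$flagged <- rep_df$sample_id %in% flagged
    utils::write.csv(rep_df, paths$outliers, row.names = FALSE)
    if (!is.null(selection)) {
      paths$selection <- file.path(out_dir, "selection.json")
      jsonlite::write_json(selection_to_list(selection), paths$selection,
                           auto_unbox = TRUE, digits = NA)
    }
    paths$model <- file.path(out_dir, "model.json")
    jsonlite::write_json(model_to_list(model, config, sel_idx,
                                       train_pp$wavelengths[sel_idx]),
                         paths$model, auto_unbox = TRUE, digits = NA)
    paths$evaluation <- file.path(out_dir, "evaluation.json")
    jsonlite::write_json(unclass(evaluation), paths$evaluation,
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(map)) {
      paths$map_csv <- file.path(out_dir, "map.csv")
      write_map_csv(map, paths$map_csv)
      paths$map_png <- file.path(out_dir, "map.png")
      render_map(map, out_path = paths$map_png)
    }
    manifest <- list(package_version = as.character(utils::packageVersion("pellspec")),
                     seed = seed,
                     config = config_to_list(config),
                     artifacts = lapply(paths, function(p)
                       list(file = basename(p),
                            md5 = unname(tools::md5sum(p)))))
    paths$manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA)
    result$paths <- paths
  }
  result
}

selection_to_list <- function(sel) {
  list(method = sel$method,
       selected_indices = sel$selected_indices,
       selected_wavelengths = round(sel$selected_wavelengths, 2),
       rmsecv_trace = sel$rmsecv_trace,
       chosen = if (!is.null(sel$chosen_run)) sel$chosen_run else sel$chosen_size,
       pls_components = sel$pls_components,
       n_selected = length(sel$selected_indices))
}

model_to_list <- function(model, config, sel_idx, wavelengths) {
  base <- list(method = config$model,
               preprocess = config$preprocess,
               selector = config$selector,
               selected_indices = sel_idx,
               wavelengths_nm = round(wavelengths, 2))
  if (inherits(model, "pls_model"))
    c(base, list(nc = model$nc, b0 = model$coefficients$b0,
                 b = model$coefficients$b))
  else
    c(base, list(n_trees = model$n_trees, min_leaf = model$min_leaf,
                 seed = model$seed))
}

config_to_list <- function(config) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$water_peaks <- as.data.frame(x$sim$water_peaks)
  x$sim$nuisance_peaks <- as.data.frame(x$sim$nuisance_peaks)
  x
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %s-%s-%s\n",
              x$config$preprocess,
              toupper(x$config$selector), toupper(x$config$model)))
  if (!is.null(x$selection))
    cat(sprintf("  selected %d / flagged %d outliers\n",
                length(x$selection$selected_indices),
                length(x$outliers$flagged)))
  print(x$evaluation)
  invisible(x)
}
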