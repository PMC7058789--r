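#' Pipeline configuration
#'
#' Collects every constant of the end-to-end analysis in one auditable
#' object: phantom cohort settings, preprocessing (target spacing, gray
#' levels), segmentation perturbation, screening thresholds, model grids,
#' and the split ratio. Configurations can be written to and read from YAML
#' with [save_config()] / [load_config()].
#'
#' @param seed master seed; every random sub-stream is derived from it.
#' @param class_sizes cases per class (SCA, MCN, IPMN order of `specs`).
#' @param specs named list of three [class_spec]s.
#' @param shape_mm,spacing phantom field of view and voxel spacing.
#' @param n_levels,distance,wavelet feature-extraction constants (see
#'   [feature_config()]).
#' @param perturb a [perturbation_spec]; its seed is ignored in favour of
#'   the master seed.
#' @param icc_threshold,cor_threshold,kw_alpha,boruta_alpha,boruta_max_iter
#'   screening thresholds.
#' @param split_ratio training fraction for the stratified split.
#' @param models which classifiers to build.
#' @param folds CV folds for grid selection.
#' @param grids optional named list of custom grids per model kind.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            class_sizes = c(76, 40, 48),
                            specs = default_class_specs(),
                            shape_mm = c(40, 40, 50),
                            spacing = c(1, 1, 5),
                            n_levels = 64L,
                            distance = 1L,
                            wavelet = "db4",
                            perturb = perturbation_spec(),
                            icc_threshold = 0.75,
                            cor_threshold = 0.75,
                            kw_alpha = 0.05,
                            boruta_alpha = 0.01,
                            boruta_max_iter = 100L,
                            split_ratio = 0.7,
                            models = c("svm", "rf", "ann"),
                            folds = 4L,
                            grids = list()) {
  models <- match.arg(models, c("svm", "rf", "ann"), several.ok = TRUE)
  stopifnot(icc_threshold >= -1, icc_threshold <= 1,
            cor_threshold >= 0, cor_threshold <= 1,
            kw_alpha > 0, kw_alpha < 1, boruta_alpha > 0, boruta_alpha < 1,
            split_ratio > 0, split_ratio <= 1)
  structure(list(seed = as.integer(seed),
                 class_sizes = as.integer(class_sizes),
                 specs = specs, shape_mm = as.numeric(shape_mm),
                 spacing = as.numeric(spacing),
                 n_levels = as.integer(n_levels),
                 distance = as.integer(distance), wavelet = wavelet,
                 perturb = perturb, icc_threshold = icc_threshold,
                 cor_threshold = cor_threshold, kw_alpha = kw_alpha,
                 boruta_alpha = boruta_alpha,
                 boruta_max_iter = boruta_max_iter,
                 split_ratio = split_ratio, models = models,
                 folds = as.integer(folds), grids = grids),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) {
      nm <- names(x)
      x <- lapply(x, strip)
      names(x) <- nm
    }
    x
  }
  yaml::write_yaml(strip(unclass(config)), path, precision = 17L)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw$specs, function(s) do.call(class_spec, s))
  raw$specs <- specs
  raw$perturb <- do.call(perturbation_spec, raw$perturb[
    c("min_px", "max_px", "n_variants", "seed")])
  do.call(pipeline_config, raw)
}

# integer-code non-numeric columns for tree/kernel models
encode_columns <- function(df) {
  for (cn in colnames(df))
    if (!is.numeric(df[[cn]])) df[[cn]] <- as.integer(as.factor(df[[cn]]))
  as.matrix(df)
}

#' Run the full phantom-to-metrics pipeline
#'
#' Executes, in order: synthetic cohort generation, stratified 70/30 split,
#' segmentation perturbation (original + variants), radiomics feature
#' extraction per segmentation set, feature screening on the training
#' cohort (ICC robustness, inter-correlation pruning, univariate tests,
#' shadow-attribute selection), cross-validated grid selection and final
#' training for each configured classifier, and per-class
#' precision/recall/F1 evaluation on training and validation cohorts. If
#' the screening stage selects nothing, modeling is skipped gracefully and
#' the manifest records why.
#'
#' @param config a [pipeline_config].
#' @param quiet suppress progress messages.
#' @return An object of class `run_manifest`: config hash, seed,
#'   stage-by-stage counts, selected features, per-model chosen
#'   hyperparameters, confusion matrices and metrics.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("stage 1/6: generating cohort (%s cases)", sum(config$class_sizes))
  cohort <- generate_cohort(config$class_sizes, config$specs, config$seed,
                            shape_mm = config$shape_mm,
                            spacing = config$spacing)
  labels <- factor(cohort$labels, levels = names(config$specs))
  clinical <- clinical_table(cohort)

  say("stage 2/6: stratified split (ratio %.2f)", config$split_ratio)
  plan <- stratified_split(labels, config$split_ratio,
                           seed = sub_seed(config$seed, 11L))

  say("stage 3/6: feature extraction over %d segmentation sets",
      config$perturb$n_variants + 1L)
  fconfig <- feature_config(n_levels = config$n_levels,
                            distance = config$distance,
                            spacing = config$spacing,
                            wavelet = config$wavelet)
  pspec <- perturbation_spec(config$perturb$min_px, config$perturb$max_px,
                             config$perturb$n_variants,
                             seed = sub_seed(config$seed, 12L))
  tables <- vector("list", pspec$n_variants + 1L)
  tables[[1]] <- extract_table(cohort, fconfig)
  for (v in seq_len(pspec$n_variants)) {
    masks <- lapply(seq_along(cohort$cases), function(k)
      perturb_mask(cohort$cases[[k]]$mask,
                   perturbation_spec(pspec$min_px, pspec$max_px,
                                     pspec$n_variants,
                                     seed = sub_seed(config$seed, 12L, k)),
                   variant_index = v))
    tables[[v + 1L]] <- extract_table(cohort, fconfig, masks = masks)
  }

  say("stage 4/6: feature screening on the training cohort")
  tr <- plan$train
  screening <- screen_pipeline(
    lapply(tables, function(t) t[tr, , drop = FALSE]),
    clinical[tr, , drop = FALSE], labels[tr],
    icc_threshold = config$icc_threshold,
    cor_threshold = config$cor_threshold,
    kw_alpha = config$kw_alpha, boruta_alpha = config$boruta_alpha,
    boruta_max_iter = config$boruta_max_iter,
    seed = sub_seed(config$seed, 13L))

  manifest <- list(config_hash = rlang::hash(config), seed = config$seed,
                   n_cases = length(cohort$cases),
                   split = list(train = plan$train,
                                validation = plan$validation),
                   n_features = ncol(tables[[1]]) - 1L,
                   screening_counts = screening$counts,
                   selected = screening$selected,
                   screening = screening,
                   models = list(), metrics = list(),
                   confusion = list())

  if (length(screening$selected) == 0) {
    manifest$notice <- "empty selection: modeling skipped"
    say("selection empty; skipping modeling")
    manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    class(manifest) <- "run_manifest"
    return(manifest)
  }

  sel_rad <- intersect(screening$selected, colnames(tables[[1]]))
  sel_cli <- intersect(screening$selected, colnames(clinical))
  xall <- cbind(tables[[1]][, sel_rad, drop = FALSE],
                clinical[, sel_cli, drop = FALSE])
  xall <- encode_columns(xall)
  x_tr <- xall[tr, , drop = FALSE]
  x_va <- xall[plan$validation, , drop = FALSE]
  y_tr <- labels[tr]
  y_va <- labels[plan$validation]
  class_order <- c("IPMN", "MCN", "SCA")

  for (mk in config$models) {
    say("stage 5/6: %s grid selection and training", toupper(mk))
    sel <- cv_select(mk, config$grids[[mk]], x_tr, y_tr,
                     folds = config$folds,
                     seed = sub_seed(config$seed, 14L, match(mk, c("svm", "rf", "ann"))))
    best <- sel$best
    fit <- switch(mk,
      svm = train_svm(x_tr, y_tr, kernel = best$kernel, C = best$C,
                      seed = sub_seed(config$seed, 15L, 1L)),
      rf = train_rf(x_tr, y_tr, n_trees = best$n_trees, mtry = best$mtry,
                    seed = sub_seed(config$seed, 15L, 2L)),
      ann = train_ann(x_tr, y_tr, hidden_units = best$hidden_units,
                      weight_decay = best$weight_decay,
                      seed = sub_seed(config$seed, 15L, 3L)))
    cm_tr <- confusion(y_tr, predict(fit, x_tr), class_order)
    cm_va <- confusion(y_va, predict(fit, x_va), class_order)
    manifest$models[[mk]] <- list(best = best, cv_table = sel$cv_table,
                                  fit = fit)
    manifest$confusion[[mk]] <- list(train = cm_tr, validation = cm_va)
    manifest$metrics[[mk]] <- list(train = metrics(cm_tr),
                                   validation = metrics(cm_va))
  }
  say("stage 6/6: done")
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d cases, %d features, hash %s\n",
              x$n_cases, x$n_features, substr(x$config_hash, 1, 10)))
  print(x$screening_counts)
  for (mk in names(x$metrics))
    cat(sprintf("%s: train OA %.4f, validation OA %.4f\n", toupper(mk),
                x$metrics[[mk]]$train$overall_accuracy,
                x$metrics[[mk]]$validation$overall_accuracy))
  invisible(x)
}

#' Formatted evaluation tables of a pipeline run
#'
#' One table per trained model, training and validation side by side, in
#' the layout produced by [format_metrics_table()]. Models missing from the
#' manifest produce a warning and a partial report.
#'
#' @param manifest a `run_manifest` from [run_pipeline()].
#' @param models models to render (default: all present).
#' @return Invisibly, a named list of character vectors (one per model).
#' @export
report_tables <- function(manifest, models = names(manifest$confusion)) {
  if (length(models) == 0 || length(manifest$confusion) == 0) {
    warning("manifest has no metrics; nothing to report")
    return(invisible(list()))
  }
  out <- list()
  for (mk in models) {
    if (is.null(manifest$confusion[[mk]])) {
      warning(sprintf("model %s missing from manifest; skipped", mk))
      next
    }
    cat(sprintf("== %s ==\n", toupper(mk)))
    out[[mk]] <- format_metrics_table(manifest$confusion[[mk]]$train,
                                      manifest$confusion[[mk]]$validation)
    cat("\n")
  }
  invisible(out)
}
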