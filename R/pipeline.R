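# End-to-end orchestration: data -> features -> per-set PCA -> forward
# selection / evaluation -> report files.

#' Build (or read) a pipeline run configuration
#'
#' The configuration is a YAML file (or an equivalent named list) with a
#' versioned schema:
#' \preformatted{
#' input:
#'   mode: phantom            # or: manifest
#'   manifest: path/to/manifest.csv     # manifest mode
#'   phantom: {n_benign: 15, n_malignant: 43, side: 64, seed: 1,
#'             class_separation: 1.0, noise_sd: 5.0}
#' glcm: {levels: 8, distance: 2}
#' pca: {threshold: 0.8, mode: per_fold}   # mode: per_fold | global
#' cv: {n_rounds: 100, n_folds: 10, stratified: true, base_seed: 1}
#' classifiers: [RF, NB, GLM]
#' max_steps: null
#' output_dir: runs/run1
#' }
#'
#' @param x path to a YAML file, or a named list of overrides.
#' @return a `run_config` list with defaults filled in.
#' @export
run_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  defaults <- list(
    schema_version = 1L,
    input = list(mode = "phantom", manifest = NULL,
                 phantom = list(n_benign = 15L, n_malignant = 43L,
                                side = 64L, seed = 1L,
                                class_separation = 1.0, noise_sd = 5.0)),
    glcm = list(levels = 8L, distance = 2L),
    pca = list(threshold = 0.8, mode = "per_fold"),
    cv = list(n_rounds = 100L, n_folds = 10L, stratified = TRUE,
              base_seed = 1L),
    classifiers = c("RF", "NB", "GLM"),
    max_steps = NULL,
    output_dir = "cesmrad_run")
  cfg <- utils::modifyList(defaults, x, keep.null = TRUE)
  class(cfg) <- "run_config"
  cfg
}

#' Statically validate a run configuration
#'
#' Checks every configuration invariant without running any stage.
#'
#' @param config a [run_config()], a named list, or a YAML path.
#' @return character vector of violations; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  config <- run_config(if (inherits(config, "run_config"))
    unclass(config) else config)
  v <- character(0)
  say <- function(msg) v <<- c(v, msg)
  if (!config$input$mode %in% c("phantom", "manifest")) {
    say("input.mode must be 'phantom' or 'manifest'")
  }
  if (config$input$mode == "manifest") {
    if (is.null(config$input$manifest)) {
      say("input.manifest path is required in manifest mode")
    } else if (!file.exists(config$input$manifest)) {
      say(paste0("input.manifest does not exist: ", config$input$manifest))
    }
  } else {
    ph <- config$input$phantom
    if (ph$n_benign + ph$n_malignant < 1) say("phantom: no lesions requested")
    if (ph$side < 8) say("phantom.side must be >= 8")
    if (ph$class_separation < 0 || ph$class_separation > 1) {
      say("phantom.class_separation must lie in [0, 1]")
    }
  }
  thr <- config$pca$threshold
  if (!is.numeric(thr) || thr <= 0 || thr >= 1) {
    say("pca.threshold must lie in (0, 1)")
  }
  if (!config$pca$mode %in% c("per_fold", "global")) {
    say("pca.mode must be 'per_fold' or 'global'")
  }
  if (config$cv$n_folds < 2) say("cv.n_folds must be >= 2 (CVConfig)")
  if (config$cv$n_rounds < 1) say("cv.n_rounds must be >= 1 (CVConfig)")
  if (!all(config$classifiers %in% c("RF", "NB", "GLM"))) {
    say("classifiers must be among RF, NB, GLM")
  }
  v
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full pipeline
#'
#' Loads the manifest (or generates phantoms), extracts the 464-feature
#' table, fits a correlation-matrix PCA per set, runs forward selection with
#' every configured classifier on each per-set candidate pool and on the
#' pooled pool, and writes all artifacts into the run directory:
#' `features.csv`, `pca_<set>.json`, `loadings_<set>.csv`,
#' `report_per_set.csv`, `report_pooled.csv` and a self-describing
#' `run.json` (configuration, seeds, package version, per-stage timings,
#' selection paths) sufficient to reproduce the run bit-for-bit.
#'
#' @param config a [run_config()] (or list/YAML path accepted by it).
#' @return the run directory path, invisibly; the `cesm_evaluation` is
#'   attached as attribute `evaluation`.
#' @export
run_pipeline <- function(config = run_config()) {
  config <- run_config(if (inherits(config, "run_config"))
    unclass(config) else config)
  violations <- validate_config(config)
  if (length(violations)) {
    stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "),
         call. = FALSE)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(config$output_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  ## stage 1: data
  if (config$input$mode == "phantom") {
    ph <- config$input$phantom
    pipeline_log(log_con, "data", sprintf(
      "generating %d+%d phantoms (side %d, seed %d, separation %.2f)",
      ph$n_benign, ph$n_malignant, ph$side, ph$seed, ph$class_separation))
    ds <- generate_phantom_dataset(phantom_config(
      ph$n_benign, ph$n_malignant, ph$side, ph$seed,
      ph$class_separation, ph$noise_sd))
    manifest <- ds$manifest
    pairs <- ds$pairs
  } else {
    pipeline_log(log_con, "data", paste("reading", config$input$manifest))
    manifest <- read_manifest(config$input$manifest)
    pairs <- load_dataset(manifest, dirname(config$input$manifest))
  }
  labels <- manifest$label
  write_manifest(manifest, file.path(config$output_dir, "manifest.csv"))
  timings["data"] <- tic() - t0; t0 <- tic()

  ## stage 2: features
  spec <- glcm_spec(config$glcm$levels, config$glcm$distance)
  pipeline_log(log_con, "features",
               sprintf("extracting 464 features for %d ROIs", length(pairs)))
  features <- extract_features(pairs, labels, spec)
  write_features(features, file.path(config$output_dir, "features.csv"))
  timings["features"] <- tic() - t0; t0 <- tic()

  ## stage 3: per-set PCA (reference fits; per-fold mode refits inside CV)
  sets <- lapply(names(feature_set_sizes), function(s)
    feature_set_matrix(features, s))
  names(sets) <- names(feature_set_sizes)
  fits <- lapply(names(sets), function(s) {
    suppressWarnings(fit_pca(sets[[s]], s, config$pca$threshold))
  })
  names(fits) <- names(sets)
  for (s in names(fits)) {
    pipeline_log(log_con, "pca", sprintf("%s: %d PCs retained", s,
                                         fits[[s]]$retained_p))
    write_pca(fits[[s]], file.path(config$output_dir,
                                   sprintf("pca_%s.json", s)))
    write.csv(summary(fits[[s]]),
              file.path(config$output_dir, sprintf("loadings_%s.csv", s)),
              row.names = FALSE)
  }
  timings["pca"] <- tic() - t0; t0 <- tic()

  ## stage 4: candidate pools
  if (config$pca$mode == "global") {
    per_set <- lapply(fits, function(f) predict(f, features))
    pooled <- do.call(cbind, unname(per_set))
  } else {
    pcs <- lapply(fits, function(f) seq_len(f$retained_p))
    per_set <- lapply(names(sets), function(s) {
      pc_candidates(sets[s], pcs[s], config$pca$threshold)
    })
    names(per_set) <- names(sets)
    pooled <- pc_candidates(sets, pcs, config$pca$threshold)
  }

  ## stage 5: selection + evaluation
  cvc <- cv_config(config$cv$n_rounds, config$cv$n_folds,
                   config$cv$stratified, config$cv$base_seed)
  pipeline_log(log_con, "evaluate", sprintf(
    "forward selection, %d x %d-fold CV, classifiers: %s, pca mode %s",
    cvc$n_rounds, cvc$n_folds, paste(config$classifiers, collapse = "/"),
    config$pca$mode))
  evaluation <- evaluate_all(per_set, pooled, labels,
                             classifiers = config$classifiers, cv = cvc,
                             max_steps = config$max_steps, verbose = TRUE)
  write_evaluation(evaluation, config$output_dir)
  timings["evaluate"] <- tic() - t0

  ## run record
  run_record <- list(
    package = "cesmrad",
    version = as.character(utils::packageVersion("cesmrad")),
    config = unclass(config),
    timings_sec = as.list(round(timings, 2)),
    retained = lapply(fits, function(f) f$retained_p),
    paths = lapply(evaluation$paths, function(p) {
      list(best_subset = p$best$subset,
           best_metrics = as.list(p$best$summary),
           steps = p$steps$subset)
    }))
  jsonlite::write_json(run_record,
                       file.path(config$output_dir, "run.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  pipeline_log(log_con, "done", sprintf("artifacts in %s", config$output_dir))
  invisible(structure(config$output_dir, evaluation = evaluation))
}
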