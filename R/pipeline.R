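#' Pipeline run configuration
#'
#' One YAML-loadable configuration drives every stage; all randomness
#' flows from the single root `seed`, so one number reproduces a run. The
#' cohort layout mirrors the reference study design: 18 patients, a
#' training split of 60 biopsies across 11 patients and a validation
#' split of 22 biopsies across the remaining 7.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Root random seed.
#' @param classifier `"dlda"`, `"dqda"` or `"svm"`.
#' @param glcm_levels GLCM gray levels.
#' @param gain_threshold Forward-selection stopping threshold.
#' @param stride Probability-map stride in voxels.
#' @param pca_in_folds Refit the reduction inside LOOCV folds.
#' @param train_patients,train_sites,valid_patients,valid_sites Cohort
#'   split sizes.
#' @param cohort Named list of overrides passed to [cohort_config()].
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("mritexture_run_"), seed = 1L,
                       classifier = "dlda", glcm_levels = 16L,
                       gain_threshold = 0.01, stride = 4L,
                       pca_in_folds = FALSE,
                       train_patients = 11L, train_sites = 60L,
                       valid_patients = 7L, valid_sites = 22L,
                       cohort = list()) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              classifier = classifier, glcm_levels = glcm_levels,
              gain_threshold = gain_threshold, stride = stride,
              pca_in_folds = pca_in_folds,
              train_patients = train_patients, train_sites = train_sites,
              valid_patients = valid_patients, valid_sites = valid_sites,
              cohort = cohort)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML path.
#' @return A `run_config` (read) or `path` (write).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

cohort_config_from <- function(config) {
  args <- config$cohort
  args$seed <- config$seed
  args$n_patients <- config$train_patients + config$valid_patients
  do.call(cohort_config, args)
}

# Short fingerprint of the scientific configuration (the output path is
# excluded: two runs of the same analysis hash identically).
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  s <- yaml::as.yaml(cfg)
  h <- 2166136261
  for (v in utf8ToInt(s)) h <- ((h %% 65536) * 16777619 + v) %% 2^31
  sprintf("%08x", as.integer(h))
}

stage_meta <- function(config) {
  list(seed = config$seed, config_hash = config_hash(config))
}

require_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop("missing upstream artifact for stage '", stage, "': ", path)
  path
}

#' Pipeline stages
#'
#' Each stage is idempotent given a fixed config and seed, reads the
#' artifacts of the stage before it, and embeds the config hash and seed
#' in what it writes.
#'
#' `run_simulate` generates and writes the training and validation
#' cohorts; `run_extract` reads the cohorts back from disk and writes the
#' two 256-column feature CSVs; `run_train` fits the
#' [tumor_content_model()] and writes the selection trace and reduction as
#' JSON; `run_validate` applies the trained model to the validation
#' features and writes zone-stratified metrics as CSV; `run_map` renders
#' a tumor-probability map for the first validation patient;
#' `run_table1_check` recomputes every reference-table metric cell from
#' reconstructed confusion matrices and writes a per-cell report.
#'
#' @param config A [run_config()].
#' @return Stage-specific artifact (invisibly where the artifact is a
#'   file): see details.
#' @export
run_simulate <- function(config) {
  cc <- cohort_config_from(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  split <- list(
    training = list(patients = seq_len(config$train_patients),
                    n_sites = config$train_sites),
    validation = list(patients = config$train_patients +
                        seq_len(config$valid_patients),
                      n_sites = config$valid_sites))
  for (nm in names(split)) {
    sp <- split[[nm]]
    per <- rep(sp$n_sites %/% length(sp$patients), length(sp$patients))
    extra <- sp$n_sites %% length(sp$patients)
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    volumes <- list(); sites <- list()
    for (j in seq_along(sp$patients)) {
      i <- sp$patients[j]
      pid <- sprintf("P%02d", i)
      pat <- generate_patient(cc, i)
      volumes[[pid]] <- pat$volumes
      set.seed(patient_seed(cc, i) + 7L)
      sites <- c(sites, sample_biopsy_sites(pat$field, cc, pid, per[j]))
    }
    dir <- file.path(config$out_dir, nm)
    write_cohort(list(volumes = volumes, sites = sites), dir)
    jsonlite::write_json(stage_meta(config),
                         file.path(dir, "meta.json"), auto_unbox = TRUE)
    message(sprintf("simulate: wrote %s cohort (%d patients, %d sites)",
                    nm, length(sp$patients), length(sites)))
  }
  invisible(config$out_dir)
}

#' @rdname run_simulate
#' @export
run_extract <- function(config) {
  for (nm in c("training", "validation")) {
    dir <- file.path(config$out_dir, nm)
    require_artifact(file.path(dir, "sites.csv"), "extract")
    cohort <- read_cohort(dir)
    feats <- extract_features(cohort$volumes, cohort$sites,
                              config$glcm_levels)
    feats$seed <- config$seed
    feats$config_hash <- config_hash(config)
    write_features(feats, file.path(config$out_dir,
                                    paste0("features_", nm, ".csv")))
    message(sprintf("extract: %s, %d sites x %d features", nm,
                    nrow(feats), length(feature_registry())))
  }
  invisible(config$out_dir)
}

#' @rdname run_simulate
#' @export
run_train <- function(config) {
  path <- require_artifact(file.path(config$out_dir,
                                     "features_training.csv"), "train")
  feats <- read_features(path)
  model <- tumor_content_model(feats, classifier = config$classifier,
                               gain_threshold = config$gain_threshold,
                               pca_in_folds = config$pca_in_folds)
  ks <- vapply(model$reduction$models, function(m)
    if (m$passthrough) length(m$columns) else m$k, 0L)
  message("train: retained components per block: ",
          paste(names(ks), ks, sep = "=", collapse = " "))
  message(sprintf("train: selected %d feature(s), LOOCV accuracy %.3f",
                  length(model$selected), model$cv_accuracy))
  write_trace(model$trace, file.path(config$out_dir, "trace.json"))
  write_reduction(model$reduction,
                  file.path(config$out_dir, "reduction.json"))
  saveRDS(model, file.path(config$out_dir, "model.rds"))
  invisible(model)
}

#' @rdname run_simulate
#' @export
run_validate <- function(config) {
  model <- readRDS(require_artifact(file.path(config$out_dir,
                                              "model.rds"), "validate"))
  feats <- read_features(require_artifact(
    file.path(config$out_dir, "features_validation.csv"), "validate"))
  res <- evaluate_on_validation(model, feats)
  res$seed <- config$seed
  res$config_hash <- config_hash(config)
  utils::write.csv(res, file.path(config$out_dir, "validation_metrics.csv"),
                   row.names = FALSE)
  message(sprintf("validate: overall accuracy %.3f on %d sites",
                  res$accuracy[res$zone == "Both"], nrow(feats)))
  invisible(res)
}

#' @rdname run_simulate
#' @export
run_map <- function(config) {
  model <- readRDS(require_artifact(file.path(config$out_dir,
                                              "model.rds"), "map"))
  dir <- file.path(config$out_dir, "validation")
  cohort <- read_cohort(dir)
  pid <- names(cohort$volumes)[1]
  slice <- cohort$sites[[1]]$slice
  map <- render_probability_map(cohort$volumes[[pid]], model, slice,
                                stride = config$stride,
                                glcm_levels = config$glcm_levels)
  write_probability_map(map, file.path(config$out_dir,
                                       paste0("probmap_", pid, ".nii.gz")))
  grDevices::png(file.path(config$out_dir,
                           paste0("probmap_", pid, ".png")),
                 width = 600, height = 600)
  plot(map, t2w = cohort$volumes[[pid]][["T2W"]])
  grDevices::dev.off()
  message(sprintf("map: %s slice %d, %d centers", pid, slice,
                  sum(map$mask)))
  invisible(map)
}

#' @rdname run_simulate
#' @export
run_table1_check <- function(config) {
  chk <- check_reference_table()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(chk$cells,
                   file.path(config$out_dir, "table1_check.csv"),
                   row.names = FALSE)
  message(sprintf("table1-check: %d/%d cells reproduced, additivity %s",
                  chk$n_matched, chk$n_cells,
                  if (chk$additivity_ok) "ok" else "FAILED"))
  invisible(chk)
}

#' Run the full pipeline
#'
#' simulate, extract, train, validate, map and table1-check in order.
#'
#' @param config A [run_config()].
#' @return List with the trained model, validation metrics and reference
#'   check.
#' @export
run_pipeline <- function(config) {
  run_simulate(config)
  run_extract(config)
  model <- run_train(config)
  val <- run_validate(config)
  map <- run_map(config)
  chk <- run_table1_check(config)
  list(model = model, validation = val, map = map, table1 = chk)
}
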