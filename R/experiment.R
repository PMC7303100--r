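#' Default project configuration
#'
#' The configuration drives the full simulate / split / train / evaluate /
#' compare pipeline. Every randomized stage derives its stream from the
#' global `seed`. The default is the desk-scale benchmark profile: an
#' 8-region x 25-pattern dataset, a 4/2/2 region split, reduced-width models
#' and 40 training epochs, sized for a single CPU core.
#'
#' @param seed global experiment seed.
#' @return A nested list (class `project_config`) with sections `data`,
#'   `split`, `model`, `train`, `evaluate`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    data = list(n_rois = 8L, n_patterns = 25L,
                magnitude_range = c(0.2, 2.4),
                start_jitter_mm = c(1.2, 1.2, 0.6)),
    split = list(n_test = 2L, n_val = 2L),
    model = list(archs = c("two_path_3d", "five_path_4d"),
                 initial_channels = c(4L, 8L, 12L), growth_rate = 8L,
                 path_pool = 2L, spatial_kernel = 3L, temporal_kernel = 2L,
                 pool_factor = 2L, input_norm = "sequence"),
    train = list(epochs = 40L, batch_size = 5L, learning_rate = 1e-3,
                 flip_augment = TRUE, w_n1 = 0, w_n2 = 0,
                 distort_p = 0, distort_px = 2L),
    evaluate = list(rotation_sweep = FALSE, distortion_sweep = FALSE)),
    class = "project_config")
}

#' Read / write a project configuration as YAML
#'
#' @param path YAML file path.
#' @param config a `project_config`.
#' @return `read_config()` returns the configuration merged over the
#'   defaults; `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_config()), user)
  class(cfg) <- "project_config"
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# short stable hash of a configuration: polynomial rolling hash over its
# canonical YAML text (stable across YAML round trips)
config_hash <- function(config) {
  bytes <- utf8ToInt(yaml::as.yaml(unclass(config)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run a full simulate / train / evaluate / compare experiment
#'
#' Builds the synthetic dataset, splits regions, trains one model per
#' requested architecture (and per loss-weight setting), evaluates each on
#' the held-out test regions, and, when two or more models are trained,
#' compares them pairwise with the paired Wilcoxon signed-rank test on
#' per-sequence rMAE. All artifacts are written under `out_dir`
#' (`data/`, `models/`, `reports/`, `logs/`), each stamped with the
#' configuration hash and seed. Re-running with the same configuration
#' reproduces the reports.
#'
#' @param config a `project_config` (see [default_config()]).
#' @param out_dir output directory; must not already contain a manifest
#'   unless `overwrite = TRUE` (no silent overwriting).
#' @param overwrite allow writing into a non-empty experiment directory.
#' @param verbose print progress.
#' @return Invisibly, a list with the trained models, reports and
#'   comparisons.
#' @export
run_experiment <- function(config = default_config(), out_dir,
                           overwrite = FALSE, verbose = TRUE) {
  hash <- config_hash(config)
  say <- function(...) if (verbose) message(sprintf(...))
  if (dir.exists(out_dir) && file.exists(file.path(out_dir, "experiment.yaml")) &&
      !overwrite)
    stop("output directory already holds an experiment; use overwrite = TRUE")
  for (d in c("data", "models", "reports", "logs"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "experiment.yaml"))

  say("[%s] simulating %d x %d sequences", hash,
      config$data$n_rois, config$data$n_patterns)
  ds <- build_dataset(n_rois = config$data$n_rois,
                      n_patterns = config$data$n_patterns,
                      seed = config$seed,
                      magnitude_range = config$data$magnitude_range,
                      start_jitter_mm = config$data$start_jitter_mm)
  utils::write.csv(ds$manifest, file.path(out_dir, "data",
                   sprintf("manifest_%s_seed%d.csv", hash, config$seed)),
                   row.names = FALSE)
  sp <- split_rois(unique(ds$manifest$roi_id),
                   n_test = config$split$n_test, n_val = config$split$n_val,
                   seed = config$seed)

  mc <- config$model
  w_n1 <- config$train$w_n1; w_n2 <- config$train$w_n2
  aug <- experiment_augment(config)
  models <- list(); reports <- list()
  for (arch in mc$archs) {
    cfg_m <- model_config(spatial_kernel = mc$spatial_kernel,
                          temporal_kernel = mc$temporal_kernel,
                          initial_channels = mc$initial_channels,
                          growth_rate = mc$growth_rate,
                          pool_factor = mc$pool_factor,
                          path_pool = mc$path_pool,
                          input_norm = mc$input_norm,
                          aux_outputs = (w_n1 > 0 || w_n2 > 0))
    tc <- train_config(epochs = config$train$epochs,
                       batch_size = config$train$batch_size,
                       learning_rate = config$train$learning_rate,
                       seed = config$seed)
    say("[%s] training %s (w_n1 = %g, w_n2 = %g)", hash, arch, w_n1, w_n2)
    model <- build_model(arch, cfg_m, seed = config$seed)
    model <- train_model(model, ds, sp, tc, w_n1 = w_n1, w_n2 = w_n2,
                         augment = aug)
    tag <- sprintf("%s_%s_seed%d", arch, hash, config$seed)
    utils::write.csv(model$history,
                     file.path(out_dir, "logs", paste0("train_", tag, ".csv")),
                     row.names = FALSE)
    saveRDS(model, file.path(out_dir, "models", paste0(tag, ".rds")))
    yaml::write_yaml(unclass(model$config),
                     file.path(out_dir, "models", paste0(tag, ".yaml")))
    rep_ <- evaluate_model(model, ds, sp$test)
    write_report(rep_, file.path(out_dir, "reports", paste0(tag, ".json")),
                 file.path(out_dir, "reports", paste0(tag, "_samples.csv")))
    say("[%s] %s: rMAE %.3f, aCC %.1f%%", hash, arch, rep_$rmae_mean,
        rep_$acc_percent)
    models[[arch]] <- model
    reports[[arch]] <- rep_
  }

  comparisons <- list()
  if (length(reports) >= 2) {
    pairs <- utils::combn(names(reports), 2, simplify = FALSE)
    comparisons <- lapply(pairs, function(p) {
      wc <- wilcoxon_compare(reports[[p[1]]]$per_sample_rmae,
                             reports[[p[2]]]$per_sample_rmae)
      c(list(model_a = p[1], model_b = p[2],
             rmae_a = reports[[p[1]]]$rmae_mean,
             rmae_b = reports[[p[2]]]$rmae_mean), wc)
    })
    jsonlite::write_json(comparisons,
      file.path(out_dir, "reports", sprintf("comparisons_%s_seed%d.json",
                                            hash, config$seed)),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(list(dataset = ds, split = sp, models = models,
                 reports = reports, comparisons = comparisons, hash = hash))
}

# training-time augmentation implied by a configuration
experiment_augment <- function(config) {
  flips <- isTRUE(config$train$flip_augment)
  pd <- config$train$distort_p
  px <- config$train$distort_px
  if (!flips && pd <= 0) return(NULL)
  function(s) {
    if (pd > 0) s <- distort_sequence(s, pd, px)
    if (flips) s <- random_flip_sequence(s)
    s
  }
}
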