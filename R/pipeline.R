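# End-to-end pipeline orchestration: synth -> simulate -> reconstruct ->
# quantify -> train -> evaluate, with structured JSONL logging and
# provenance hashes. This is the programmatic core behind the `picslim`
# command-line script (inst/cli/picslim.R).

#' Validated pipeline configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; every stage derives its own stream from it.
#' @param n_per_class synthetic maps per class.
#' @param params a [fiber_texture_params()].
#' @param beta_scale,noise_sd forward-model settings for the optics stage.
#' @param wavelength,refractive_increment dry-mass constants (um, um^3/pg).
#' @param task,epochs,batch_size classifier settings.
#' @param n_train,n_val,n_test split sizes; defaults use 60/20/20 of the
#'   generated items.
#' @param write_tiles write every generated map to `out_dir` as float TIFF.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, n_per_class = 12L,
                       params = fiber_texture_params(image_shape = c(48, 64), seed = seed),
                       beta_scale = 0.5, noise_sd = 0,
                       wavelength = 0.55, refractive_increment = 0.2,
                       task = "diet", epochs = 5L, batch_size = 16L,
                       n_train = NULL, n_val = NULL, n_test = NULL,
                       write_tiles = FALSE) {
  if (wavelength <= 0 || refractive_increment <= 0 || beta_scale <= 0) {
    stop("physical constants must be positive", call. = FALSE)
  }
  n_items <- 4L * as.integer(n_per_class)
  if (is.null(n_train)) n_train <- floor(0.6 * n_items)
  if (is.null(n_val)) n_val <- floor(0.2 * n_items)
  if (is.null(n_test)) n_test <- n_items - n_train - n_val
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_per_class = as.integer(n_per_class), params = params,
                 beta_scale = beta_scale, noise_sd = noise_sd,
                 wavelength = wavelength,
                 refractive_increment = refractive_increment,
                 task = task, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 n_train = n_train, n_val = n_val, n_test = n_test,
                 write_tiles = isTRUE(write_tiles)),
            class = "run_config")
}

log_stage <- function(log_path, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      file = log_path, append = TRUE, sep = "")
}

#' Run the full synthetic pipeline
#'
#' Generates a labeled interferogram dataset, reconstructs every phase
#' map through the four-frame inversion, computes dry-mass and histogram
#' summaries, trains the requested classifier and evaluates it on the
#' test split. Artifacts (manifest CSV, overlap table CSV, metrics JSON,
#' optional per-map TIFFs) and a line-delimited JSON log land in
#' `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the dataset, reconstruction RMS error,
#'   overlap table, trained model and test evaluation.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.jsonl")

  # synth + forward optics
  ids <- generate_interferogram_dataset(config$params, config$n_per_class,
                                        beta_scale = config$beta_scale,
                                        noise_sd = config$noise_sd,
                                        seed = config$seed)
  log_stage(log_path, "synth+simulate", seed = config$seed,
            n_items = nrow(ids$items), hash = object_hash(ids$items))

  # reconstruction: recovered scattered-field phase vs ground truth
  recon <- lapply(ids$stacks, reconstruct_delta_phi)
  rms <- sqrt(mean(vapply(seq_along(recon), function(i) {
    mean((recon[[i]]$delta_phi - wrap_phase(ids$phases[[i]]$phi))^2)
  }, numeric(1))))
  log_stage(log_path, "reconstruct", rms_error_rad = rms)

  # quantify: per-class pooled histograms + dry-mass table
  by_class <- split(seq_len(nrow(ids$items)), ids$items$class)
  class_maps <- lapply(by_class, function(ix) ids$phases[ix])
  overlaps <- group_pairwise_overlaps(class_maps)
  utils::write.csv(overlaps, file.path(config$out_dir, "class_overlaps.csv"),
                   row.names = FALSE)
  mass_rows <- lapply(seq_len(nrow(ids$items)), function(i) {
    dm <- phase_to_dry_mass(ids$phases[[i]], config$wavelength,
                            config$refractive_increment)
    mk <- myelin_mask(ids$phases[[i]])
    st <- masked_dry_mass_stats(dm, mk)
    data.frame(id = ids$items$id[i], class = ids$items$class[i],
               threshold_rad = mk$threshold,
               total_mass_pg = st$total_mass_pg,
               mean_density_pg_um2 = st$mean_density_pg_um2,
               area_um2 = st$area_um2)
  })
  utils::write.csv(do.call(rbind, mass_rows),
                   file.path(config$out_dir, "dry_mass.csv"), row.names = FALSE)
  log_stage(log_path, "quantify", overlap_hash = object_hash(overlaps))

  if (config$write_tiles) {
    tile_dir <- file.path(config$out_dir, "maps")
    dir.create(tile_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(ids$items))) {
      write_image(file.path(tile_dir, paste0(ids$items$id[i], ".tif")),
                  ids$phases[[i]])
    }
  }

  # classify
  ds <- structure(list(items = ids$items, images = ids$phases),
                  class = "labeled_dataset")
  ds <- split_dataset(ds, config$n_train, config$n_val, config$n_test,
                      seed = derive_seed(config$seed, 9L), stratify = TRUE)
  utils::write.csv(ds$items, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  cfg <- classifier_config(task = config$task, epochs = config$epochs,
                           batch_size = config$batch_size,
                           seed = derive_seed(config$seed, 10L))
  model <- train_classifier(ds, cfg)
  ev <- evaluate(model, ds, "test")
  metrics <- list(task = config$task, history = model$history,
                  test_accuracy = ev$accuracy, test_loss = ev$mean_loss,
                  confusion_counts = unname(as.data.frame(ev$confusion$counts)),
                  reconstruction_rms_rad = rms)
  jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  log_stage(log_path, "train+evaluate", test_accuracy = ev$accuracy,
            model_hash = object_hash(model$layers))
  invisible(list(dataset = ds, reconstruction_rms = rms, overlaps = overlaps,
                 model = model, evaluation = ev))
}

#' Export a phase histogram as CSV
#'
#' Columns `bin_left`, `bin_right`, `count`, `fraction`.
#'
#' @param hist a [phase_histogram()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "phase_histogram"))
  k <- length(hist$counts)
  utils::write.csv(data.frame(bin_left = hist$bin_edges[seq_len(k)],
                              bin_right = hist$bin_edges[seq_len(k) + 1],
                              count = hist$counts,
                              fraction = hist$normalized),
                   path, row.names = FALSE)
  invisible(path)
}
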