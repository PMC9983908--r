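## Serialization: spectra as long-format CSV and 8-bit grayscale PNG,
## centroid tables and manifests as CSV, run configuration as YAML,
## provenance as JSON. Readers are schema-tolerant (header sniffing)
## because the layout of third-party spectral CSVs varies.

.match_col <- function(nms, candidates) {
  hit <- which(tolower(nms) %in% candidates)
  if (!length(hit)) NULL else hit[1]
}

#' Write / read a 2D spectrum as long-format CSV
#'
#' Columns `t1, t2, intensity`, one row per grid cell, floats printed at
#' 9 significant digits.  The reader accepts any case and the synonyms
#' `value`/`amplitude` for the intensity column, and rebuilds the grids
#' from the unique coordinate values.
#'
#' @param spec a [spectrum2d()].
#' @param path file path.
#' @return `read_spectrum_csv` returns a [spectrum2d()].
#' @export
write_spectrum_csv <- function(spec, path) {
  d <- data.frame(
    t1 = rep(spec$t1_grid, times = length(spec$t2_grid)),
    t2 = rep(spec$t2_grid, each = length(spec$t1_grid)),
    intensity = as.vector(spec$intensity))
  d[] <- lapply(d, function(x) formatC(x, digits = 9, format = "g"))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  i1 <- .match_col(names(d), c("t1", "t1_s", "t1.s."))
  i2 <- .match_col(names(d), c("t2", "t2_s", "t2.s."))
  iv <- .match_col(names(d), c("intensity", "value", "amplitude"))
  if (is.null(i1) || is.null(i2) || is.null(iv)) {
    stop_arg("spectrum CSV needs t1, t2 and intensity columns; found: ",
             paste(names(d), collapse = ", "))
  }
  bad <- which(!stats::complete.cases(d[, c(i1, i2, iv)]))
  if (length(bad)) stop_arg("malformed spectrum CSV row(s): line ", bad[1] + 1L)
  t1 <- sort(unique(d[[i1]]))
  t2 <- sort(unique(d[[i2]]))
  X <- matrix(0, length(t1), length(t2))
  X[cbind(match(d[[i1]], t1), match(d[[i2]], t2))] <- d[[iv]]
  spectrum2d(t1, t2, pmax(X, 0), metadata = list(source = path))
}

#' Write / read a spectrum as 8-bit grayscale PNG
#'
#' Intensity is max-normalized per spectrum; T1 runs along image rows,
#' ascending downward.  The round trip is lossy only by the 8-bit
#' quantization (per-pixel error at most 1/255 of the maximum).
#'
#' @param spec a [spectrum2d()].
#' @param path file path.
#' @return `read_spectrum_png` returns the intensity matrix in `[0, 1]`.
#' @export
write_spectrum_png <- function(spec, path) {
  X <- spec$intensity
  mx <- max(X)
  if (mx > 0) X <- X / mx
  png::writePNG(X, target = path)
  invisible(path)
}

#' @rdname write_spectrum_png
#' @export
read_spectrum_png <- function(path) {
  X <- png::readPNG(path)
  if (length(dim(X)) == 3L) X <- X[, , 1]
  X
}

#' Write / read a weighted-centroid table as CSV
#'
#' Columns `sample_id, class_label, t1, t2`.  The reader sniffs headers
#' case-insensitively and accepts `class`, `label` or `celltype` for the
#' class column, so centroid tables from other tools can be fed straight
#' into the SVM track.
#'
#' @param centroids `data.frame` as produced by [centroid_table()].
#' @param path file path.
#' @return `read_centroids_csv` returns the centroid `data.frame`.
#' @export
write_centroids_csv <- function(centroids, path) {
  utils::write.csv(centroids[, c("sample_id", "class_label", "t1", "t2")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centroids_csv
#' @export
read_centroids_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  is_ <- .match_col(names(d), c("sample_id", "sample", "id", "name"))
  ic <- .match_col(names(d), c("class_label", "class", "label", "celltype", "cell_type"))
  i1 <- .match_col(names(d), c("t1", "centroid_t1", "t1_s"))
  i2 <- .match_col(names(d), c("t2", "centroid_t2", "t2_s"))
  if (is.null(ic) || is.null(i1) || is.null(i2)) {
    stop_arg("centroid CSV needs class and t1/t2 columns; found: ",
             paste(names(d), collapse = ", "))
  }
  bad <- which(!is.finite(d[[i1]]) | !is.finite(d[[i2]]))
  if (length(bad)) stop_arg("malformed centroid CSV row(s): line ", bad[1] + 1L)
  data.frame(
    sample_id = if (is.null(is_)) sprintf("row_%04d", seq_len(nrow(d))) else as.character(d[[is_]]),
    class_label = as.character(d[[ic]]),
    t1 = d[[i1]], t2 = d[[i2]], stringsAsFactors = FALSE)
}

#' Write / read time-domain data as CSV with a JSON sidecar
#'
#' Long format `ti_index, echo_index, amplitude`; the sidecar
#' `<path>.json` stores the TI vector, echo times and sample metadata.
#'
#' @param td a [time_domain_data()].
#' @param path CSV file path.
#' @return `read_timedomain_csv` returns a [time_domain_data()].
#' @export
write_timedomain_csv <- function(td, path) {
  d <- data.frame(
    ti_index = rep(seq_along(td$ti_vector), times = length(td$echo_times)),
    echo_index = rep(seq_along(td$echo_times), each = length(td$ti_vector)),
    amplitude = as.vector(td$amplitudes))
  utils::write.csv(d, path, row.names = FALSE)
  md <- td$metadata
  md$jittered_components <- NULL
  jsonlite::write_json(
    list(ti_vector = td$ti_vector, echo_times = td$echo_times, metadata = md),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_timedomain_csv
#' @export
read_timedomain_csv <- function(path) {
  d <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- length(side$ti_vector); m <- length(side$echo_times)
  A <- matrix(0, n, m)
  A[cbind(d$ti_index, d$echo_index)] <- d$amplitude
  time_domain_data(side$ti_vector, side$echo_times, A,
                   metadata = as.list(side$metadata))
}

#' Default run configuration
#'
#' Aggregates the tunable constants of every stage in one nested list,
#' serializable as YAML: acquisition protocol, reconstruction grids and
#' ranks, feature thresholds and the exact published crop window
#' (3.0079 s, 0.4062 s), augmentation presets, and classifier settings.
#'
#' @param seed global seed.
#' @return Nested configuration list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    protocol = list(n_inversions = 32L, ti_min = 0.005, ti_max = 15.0,
                    n_echoes = 5000L, echo_spacing_te = 0.003,
                    points_per_echo = 40L, noise_sigma = 0.0632),
    reconstruction = list(grid_n = 300L, t1_range = c(1e-3, 15),
                          t2_range = c(1e-3, 5), n_t2 = 256L, pca_rank = 8L,
                          r1 = 16L, r2 = 32L, alpha = 1e-3),
    features = list(threshold_frac = 0.05, min_area = 4L,
                    min_intensity_frac = 0.01, media_t1_min = 2,
                    crop_t1_max = 3.0079, crop_t2_max = 0.4062),
    augmentation = list(msc = list(shift_std = 0.005, stretch_std = 0.01, factor = 5L),
                        cell_line = list(shift_std = 0.001, stretch_std = 0.01, factor = 5L)),
    classifier = list(svm = list(degree = 2L, coef0 = 0, train_fraction = 0.5,
                                 replicates = 300L),
                      ann = list(input_size = 32L, epochs = 12L,
                                 learning_rate = 1e-3, batch_size = 16L,
                                 replicates = 10L))
  ), class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config a `run_config` list.
#' @param path file path.
#' @return `read_run_config` returns the configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

## cheap stable hash of an R object (hex string) for provenance records
config_hash <- function(x) {
  s <- yaml::as.yaml(x)
  h <- 0
  for (ci in utf8ToInt(s)) h <- (h * 131 + ci) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write a provenance record for a pipeline stage
#'
#' JSON with the configuration hash, the seeds in play, package and R
#' versions, a timestamp and free-form extras, so every artifact is
#' traceable to the run that produced it.
#'
#' @param path output JSON path.
#' @param config the `run_config` in force.
#' @param seed the root seed.
#' @param extra named list of stage-specific entries.
#' @return The record, invisibly.
#' @export
write_provenance <- function(path, config, seed, extra = list()) {
  rec <- c(list(
    config_hash = config_hash(config),
    seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("relaxcell")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(rec)
}

#' Dataset manifest listing artifacts on disk
#'
#' @param rows `data.frame` with columns `path`, `sample_id`,
#'   `class_label`, `stage` (one of raw, spectrum, cropped, augmented),
#'   `parent_id`, `seed`.
#' @param path CSV path.
#' @param check_paths verify at load that every referenced file exists.
#' @return `read_dataset_manifest` returns the validated `data.frame`.
#' @export
write_dataset_manifest <- function(rows, path) {
  stages <- c("raw", "spectrum", "cropped", "augmented")
  if (!all(rows$stage %in% stages)) {
    stop_arg("stage must be one of: ", paste(stages, collapse = ", "))
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_manifest
#' @export
read_dataset_manifest <- function(path, check_paths = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (check_paths) {
    missing <- d$path[!file.exists(d$path)]
    if (length(missing)) {
      stop_arg("manifest references missing file(s): ",
               paste(utils::head(missing, 3), collapse = ", "))
    }
    aug <- d[d$stage == "augmented", ]
    bad <- setdiff(aug$parent_id, d$sample_id)
    if (length(bad)) stop_arg("unresolvable parent_id(s): ",
                              paste(utils::head(bad, 3), collapse = ", "))
  }
  d
}

#' Export a trained network architecture as JSON
#'
#' A portable description of the layer stack (types, shapes, parameter
#' counts) in the spirit of neural-network exchange formats, without the
#' weights.
#'
#' @param model a `relaxcell_ann`.
#' @param path output JSON path.
#' @return The description list, invisibly.
#' @export
export_ann_architecture <- function(model, path) {
  desc <- list(
    variant = model$arch$variant,
    input_size = model$arch$input_size,
    n_classes = model$n_classes,
    optimizer = model$arch$optimizer,
    layers = lapply(model$layers, function(l) {
      out <- list(type = l$type)
      if (l$type == "conv") out <- c(out, list(in_channels = l$Cin, out_channels = l$Cout,
                                               kernel = c(3L, 3L)))
      if (l$type == "dense") out <- c(out, list(n_in = l$n_in, n_out = l$n_out))
      if (l$type == "dropout") out <- c(out, list(rate = l$rate))
      out
    }))
  jsonlite::write_json(desc, path, auto_unbox = TRUE)
  invisible(desc)
}
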