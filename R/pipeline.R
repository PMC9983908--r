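#' Simulate and reconstruct a cohort in one call
#'
#' Convenience wrapper: simulates every manifest replicate and runs the
#' full reconstruction chain, returning the list of spectra with sample
#' metadata attached.  Reduced grid sizes (e.g. 100) keep exploratory
#' runs fast; 300 reproduces the full-resolution setting.
#'
#' @param manifest a [cohort_manifest()].
#' @param phenotypes phenotype library.
#' @param protocol acquisition protocol.
#' @param grid_n reconstruction grid size per dimension.
#' @param alpha Tikhonov weight (or `"auto"`).
#' @param ... further arguments for [reconstruct_spectrum()].
#' @return Named list of [spectrum2d()].
#' @export
cohort_spectra <- function(manifest, phenotypes = phenotype_library(),
                           protocol = default_protocol(), grid_n = 100L,
                           alpha = 1e-3, ...) {
  cohort <- simulate_cohort(manifest, phenotypes, protocol)
  grid <- spectrum_grid(grid_n)
  lapply(cohort, function(td) {
    spec <- suppressWarnings(
      reconstruct_spectrum(td, grid = grid, alpha = alpha, ...))
    spec$metadata$sample_id <- td$metadata$sample_id
    spec$metadata$class_label <- td$metadata$class_label
    spec
  })
}

#' SVM accuracy for a set of class combinations
#'
#' Runs [run_svm_replicates()] on the rows of a centroid table
#' restricted to each requested class combination — the evaluation grid
#' of the published accuracy-versus-class-count comparison.  Works on
#' any centroid table, including ones read with [read_centroids_csv()]
#' from a local copy of the original study's supplementary data.
#'
#' @param centroids `data.frame` with `t1`, `t2`, `class_label`.
#' @param combinations list of character vectors of class labels.
#' @param config an [svm_config()].
#' @return `data.frame` with `classes`, `k`, `mean_accuracy`,
#'   `sd_accuracy`.
#' @export
svm_benchmark <- function(centroids, combinations,
                          config = svm_config()) {
  rows <- lapply(combinations, function(ss) {
    sub <- centroids[centroids$class_label %in% ss, , drop = FALSE]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "bench", paste(ss, collapse = ","))
    res <- run_svm_replicates(sub, cfg)
    data.frame(classes = paste(ss, collapse = ","), k = length(ss),
               mean_accuracy = res$mean, sd_accuracy = res$sd)
  })
  do.call(rbind, rows)
}

#' Accuracy as a function of class count
#'
#' For each `k`, evaluates the mean replicate SVM accuracy on the first
#' (or best, if `search`) combination of `k` classes, reproducing the
#' monotone accuracy degradation with growing class count.
#'
#' @param centroids centroid table.
#' @param ks class counts to evaluate.
#' @param config an [svm_config()] (use a reduced `replicates` for
#'   exploratory runs).
#' @param search if `TRUE`, exhaustively search combinations per `k`
#'   (expensive) and report the best; otherwise evaluate nested subsets
#'   of classes ordered by sample count.
#' @return `data.frame` with `k`, `classes`, `mean_accuracy`,
#'   `sd_accuracy`.
#' @export
class_count_sweep <- function(centroids, ks = 2:10,
                              config = svm_config(replicates = 10L),
                              search = FALSE) {
  classes <- names(sort(table(centroids$class_label), decreasing = TRUE))
  rows <- lapply(ks, function(k) {
    if (search) {
      best <- combination_search(centroids, k, config)[1, ]
      data.frame(k = k, classes = best$classes,
                 mean_accuracy = best$mean_accuracy,
                 sd_accuracy = best$sd_accuracy)
    } else {
      ss <- classes[seq_len(k)]
      b <- svm_benchmark(centroids, list(ss), config)
      data.frame(k = k, classes = b$classes,
                 mean_accuracy = b$mean_accuracy, sd_accuracy = b$sd_accuracy)
    }
  })
  do.call(rbind, rows)
}

#' Path to a local copy of the original study's supplementary data
#'
#' The package can re-score the published centroid tables and spectral
#' maps when a local copy of the supplementary archives is unpacked
#' under `inst/extdata/supplementary/` (no public accession exists to
#' download them from).  Returns `NULL` when the directory is absent.
#'
#' @return Directory path or `NULL`.
#' @export
supplementary_data_dir <- function() {
  p <- system.file("extdata", "supplementary", package = "relaxcell")
  if (nzchar(p) && dir.exists(p)) p else NULL
}
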