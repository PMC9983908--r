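#' Detect peaks in a T1/T2 spectrum
#'
#' Thresholds the spectrum at a fraction of its maximum and extracts
#' 8-connected components of the suprathreshold mask, discarding
#' components that are too small or carry too little of the total
#' intensity.  Returned regions are sorted by total intensity,
#' descending, and carry their intensity-weighted centroid.
#'
#' @param spec a [spectrum2d()].
#' @param threshold_frac mask threshold as a fraction of the spectrum
#'   maximum, in (0, 1).
#' @param min_area minimum component size in grid cells.
#' @param min_intensity_frac minimum component intensity as a fraction
#'   of total spectrum intensity.
#' @return List of `peak_region` objects (possibly empty).  Each region
#'   has fields `cells` (linear indices into the intensity matrix),
#'   `total_intensity`, `bbox` (row/col index ranges), `centroid_t1`,
#'   `centroid_t2` and `tag` (initially `"unassigned"`).
#' @export
detect_peaks <- function(spec, threshold_frac = 0.05, min_area = 4L,
                         min_intensity_frac = 0.01) {
  stopifnot(inherits(spec, "spectrum2d"))
  if (!(threshold_frac > 0 && threshold_frac < 1)) {
    stop_arg("`threshold_frac` must be in (0, 1)")
  }
  X <- spec$intensity
  mx <- max(X)
  if (mx <= 0) return(list())
  mask <- X >= threshold_frac * mx
  cells <- which(mask)
  if (!length(cells)) return(list())
  lab <- .label_components8(mask, cells)
  total <- sum(X)
  regions <- lapply(split(cells, lab), function(cc) {
    ti <- sum(X[cc])
    rows <- ((cc - 1L) %% nrow(X)) + 1L
    cols <- ((cc - 1L) %/% nrow(X)) + 1L
    r <- structure(
      list(cells = cc, total_intensity = ti,
           bbox = list(rows = range(rows), cols = range(cols)),
           centroid_t1 = NA_real_, centroid_t2 = NA_real_,
           tag = "unassigned"),
      class = "peak_region"
    )
    cen <- weighted_centroid(r, spec)
    r$centroid_t1 <- cen[["t1"]]
    r$centroid_t2 <- cen[["t2"]]
    r
  })
  keep <- vapply(regions, function(r) {
    length(r$cells) >= min_area && r$total_intensity >= min_intensity_frac * total
  }, TRUE)
  regions <- regions[keep]
  regions[order(vapply(regions, `[[`, 0, "total_intensity"), decreasing = TRUE)]
}

## 8-connected component labels of the TRUE cells of `mask`.
## Built as graph components over the 4 forward neighbour offsets.
.label_components8 <- function(mask, cells) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- matrix(0L, nr, nc)
  idx[cells] <- seq_along(cells)
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    di <- off[1]; dj <- off[2]
    rows <- ((cells - 1L) %% nr) + 1L
    cols <- ((cells - 1L) %/% nr) + 1L
    ri <- rows + di; cj <- cols + dj
    ok <- ri >= 1L & ri <= nr & cj >= 1L & cj <= nc
    nb <- idx[cbind(ri[ok], cj[ok])]
    has <- nb > 0L
    edges <- c(edges, rbind(idx[cbind(rows[ok][has], cols[ok][has])], nb[has]))
  }
  g <- igraph::make_graph(edges = edges, n = length(cells), directed = FALSE)
  igraph::components(g)$membership
}

#' Tag detected peaks as cell, media or lipid
#'
#' The media peak sits at long T1 (about 2-3 s) in every sample, while
#' cell peaks vary by cell type at shorter T1.  Regions whose centroid
#' T1 falls in the media window are tagged `media`; the rest are tagged
#' `cell`, except that when two or more peaks occupy the cell window the
#' shortest-T1 one is tagged `lipid` (the extra peak adipogenic
#' differentiation produces).
#'
#' @param regions list of peak regions from [detect_peaks()].
#' @param media_t1_min lower T1 bound of the media window in seconds.
#' @return The regions with tags assigned (deterministic).
#' @export
tag_peaks <- function(regions, media_t1_min = 2) {
  if (!length(regions)) return(regions)
  t1s <- vapply(regions, `[[`, 0, "centroid_t1")
  is_media <- t1s >= media_t1_min
  for (i in seq_along(regions)) {
    regions[[i]]$tag <- if (is_media[i]) "media" else "cell"
  }
  cell_idx <- which(!is_media)
  if (length(cell_idx) >= 2) {
    lip <- cell_idx[which.min(t1s[cell_idx])]
    regions[[lip]]$tag <- "lipid"
  }
  regions
}

#' Intensity-weighted centroid of a peak region
#'
#' Mean (T1, T2) coordinate over the region's mask, weighted by spectrum
#' intensity, computed in linear seconds.
#'
#' @param region a peak region.
#' @param spec the [spectrum2d()] the region was detected in.
#' @return Named numeric vector `c(t1 = , t2 = )` in seconds.
#' @export
weighted_centroid <- function(region, spec) {
  cc <- region$cells
  w <- spec$intensity[cc]
  tw <- sum(w)
  if (tw <= 0) stop_arg("region has zero total intensity")
  nr <- nrow(spec$intensity)
  rows <- ((cc - 1L) %% nr) + 1L
  cols <- ((cc - 1L) %/% nr) + 1L
  c(t1 = sum(w * spec$t1_grid[rows]) / tw,
    t2 = sum(w * spec$t2_grid[cols]) / tw)
}

#' Crop a spectrum to the cell-peak window
#'
#' Restricts the spectrum to T1 at most `t1_max` and T2 at most
#' `t2_max`; the defaults are the published cell-window bounds
#' (3.0079 s, 0.4062 s), which exclude the media peak before network
#' training.
#'
#' @param spec a [spectrum2d()].
#' @param t1_max,t2_max window upper bounds in seconds.
#' @return The cropped [spectrum2d()].
#' @export
crop_to_cell_window <- function(spec, t1_max = 3.0079, t2_max = 0.4062) {
  stopifnot(inherits(spec, "spectrum2d"))
  i <- which(spec$t1_grid <= t1_max)
  j <- which(spec$t2_grid <= t2_max)
  if (!length(i) || !length(j)) stop_arg("crop window does not overlap the grid")
  md <- spec$metadata
  md$crop_window <- c(t1_max = t1_max, t2_max = t2_max)
  spectrum2d(spec$t1_grid[i], spec$t2_grid[j],
             spec$intensity[i, j, drop = FALSE], metadata = md)
}

#' Weighted-centroid table for a cohort of spectra
#'
#' For every spectrum, detects and tags peaks and records the
#' intensity-weighted centroid of the most intense cell-tagged peak —
#' the feature pair the SVM classifies.  Samples without any cell peak
#' (e.g. media-only controls) are not raised as errors; they are listed
#' in the `exclusions` attribute.
#'
#' @param spectra list of [spectrum2d()] objects whose metadata carries
#'   `sample_id` and `class_label`.
#' @param ... passed to [detect_peaks()].
#' @param media_t1_min passed to [tag_peaks()].
#' @return `data.frame` with columns `sample_id`, `class_label`, `t1`,
#'   `t2`; attribute `exclusions` is a data.frame of skipped samples.
#' @export
centroid_table <- function(spectra, ..., media_t1_min = 2) {
  rows <- list()
  excl <- list()
  for (spec in spectra) {
    sid <- spec$metadata$sample_id %||% NA_character_
    cls <- spec$metadata$class_label %||% spec$metadata$phenotype %||% NA_character_
    regions <- tag_peaks(detect_peaks(spec, ...), media_t1_min = media_t1_min)
    cells <- Filter(function(r) r$tag == "cell", regions)
    if (!length(cells)) {
      excl[[length(excl) + 1L]] <- data.frame(
        sample_id = sid, reason = "no cell-tagged peak")
      next
    }
    best <- cells[[1]]  # detect_peaks sorts by intensity, descending
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sid, class_label = cls,
      t1 = best$centroid_t1, t2 = best$centroid_t2)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), class_label = character(),
               t1 = numeric(), t2 = numeric())
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(sample_id = character(), reason = character())
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
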