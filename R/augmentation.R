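#' Augmentation parameters
#'
#' Controls the peak-based augmentation: every detected peak is randomly
#' translated (shift, std dev in seconds, applied in linear time
#' coordinates) and rescaled about its centroid (stretch, std dev as a
#' fraction of the peak's original width), independently per dimension,
#' and the procedure is repeated `factor` times per input spectrum.
#'
#' @param shift_std_t1,shift_std_t2 shift std dev in seconds per
#'   dimension (usually kept identical).
#' @param stretch_std stretch std dev as a fraction (0.01 = 1 %).
#' @param factor number of augmented copies per spectrum (>= 0).
#' @param seed integer seed.
#' @param keep_original also return the unmodified spectrum, flagged.
#' @return Object of class `augmentation_params`.
#' @export
augmentation_params <- function(shift_std_t1 = 0.005,
                                shift_std_t2 = shift_std_t1,
                                stretch_std = 0.01,
                                factor = 5L, seed = 1L,
                                keep_original = TRUE) {
  if (shift_std_t1 < 0 || shift_std_t2 < 0 || stretch_std < 0) {
    stop_arg("standard deviations must be >= 0")
  }
  if (factor < 0) stop_arg("`factor` must be >= 0")
  structure(list(shift_std_t1 = shift_std_t1, shift_std_t2 = shift_std_t2,
                 stretch_std = stretch_std, factor = as.integer(factor),
                 seed = as.integer(seed), keep_original = keep_original),
            class = "augmentation_params")
}

#' Published augmentation presets
#'
#' The parameter values selected in the source study after the sweep
#' over shift/stretch combinations: 1 % stretch with 5 ms shift for the
#' MSC task, 1 % stretch with 1 ms shift for the cell-line task, both at
#' augmentation factor 5.
#'
#' @param task `"msc"` or `"cell_line"`.
#' @param ... overrides passed to [augmentation_params()].
#' @return An `augmentation_params`.
#' @export
augmentation_preset <- function(task = c("msc", "cell_line"), ...) {
  task <- match.arg(task)
  shift <- if (task == "msc") 0.005 else 0.001
  augmentation_params(shift_std_t1 = shift, stretch_std = 0.01, ...)
}

stop_boundary <- function(msg) {
  stop(structure(class = c("relaxcell_boundary_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

## Bilinear interpolation of the peak-only image `P` (on the spectrum's
## log-spaced grid, linear-second coordinates) at query coordinates
## `q1` (length n) x `q2` (length m); queries outside the grid give 0.
.interp_peak <- function(P, g1, g2, q1, q2) {
  n <- length(g1); m <- length(g2)
  ix <- findInterval(q1, g1)
  jx <- findInterval(q2, g2)
  in1 <- q1 >= g1[1] & q1 <= g1[n]
  in2 <- q2 >= g2[1] & q2 <= g2[m]
  i0 <- pmin(pmax(ix, 1L), n - 1L)
  j0 <- pmin(pmax(jx, 1L), m - 1L)
  w <- (q1 - g1[i0]) / (g1[i0 + 1L] - g1[i0])
  v <- (q2 - g2[j0]) / (g2[j0 + 1L] - g2[j0])
  w[!in1] <- 0; v[!in2] <- 0
  rowlo <- P[i0, , drop = FALSE] * (1 - w) + P[i0 + 1L, , drop = FALSE] * w
  out <- t(t(rowlo[, j0, drop = FALSE]) * (1 - v) +
           t(rowlo[, j0 + 1L, drop = FALSE]) * v)
  out[!in1, ] <- 0
  out[, !in2] <- 0
  out
}

## Peak-only image and complementary background of a region.
.split_peak <- function(spec, region) {
  P <- matrix(0, nrow(spec$intensity), ncol(spec$intensity))
  P[region$cells] <- spec$intensity[region$cells]
  list(peak = P, base = spec$intensity - P)
}

## Linear-coordinate support of the region, per dimension.
.region_support <- function(spec, region) {
  list(t1 = spec$t1_grid[region$bbox$rows],
       t2 = spec$t2_grid[region$bbox$cols])
}

.rebuild_spectrum <- function(spec, base, peak_new, peak_mass) {
  peak_new <- pmax(peak_new, 0)
  s <- sum(peak_new)
  if (s > 0) peak_new <- peak_new * (peak_mass / s)
  spectrum2d(spec$t1_grid, spec$t2_grid, base + peak_new,
             metadata = spec$metadata)
}

#' Shift a peak in linear time coordinates
#'
#' Translates the region's intensity by `(dt1, dt2)` seconds, leaving
#' everything outside the region untouched.  The translated peak is
#' resampled onto the log-spaced grid by bilinear interpolation in
#' linear coordinates and renormalized so the peak's total intensity is
#' conserved.
#'
#' @param spec a [spectrum2d()].
#' @param region a peak region from [detect_peaks()].
#' @param dt1,dt2 shift in seconds per dimension.
#' @return The shifted [spectrum2d()].
#' @export
shift_peak <- function(spec, region, dt1, dt2) {
  sup <- .region_support(spec, region)
  g1 <- spec$t1_grid; g2 <- spec$t2_grid
  if (sup$t1[1] + dt1 < g1[1] || sup$t1[2] + dt1 > g1[length(g1)] ||
      sup$t2[1] + dt2 < g2[1] || sup$t2[2] + dt2 > g2[length(g2)]) {
    stop_boundary("shift moves peak support outside the grid")
  }
  parts <- .split_peak(spec, region)
  shifted <- .interp_peak(parts$peak, g1, g2, g1 - dt1, g2 - dt2)
  .rebuild_spectrum(spec, parts$base, shifted, region$total_intensity)
}

#' Stretch a peak about its centroid
#'
#' Rescales the region's intensity about its weighted centroid by
#' factors `(1 + s1, 1 + s2)` in linear coordinates, renormalized so the
#' peak's total intensity is conserved.
#'
#' @param spec a [spectrum2d()].
#' @param region a peak region.
#' @param s1,s2 stretch fractions per dimension, `(1 + s) > 0`.
#' @return The stretched [spectrum2d()].
#' @export
stretch_peak <- function(spec, region, s1, s2) {
  if (1 + s1 <= 0 || 1 + s2 <= 0) stop_arg("(1 + s) must be positive")
  c1 <- region$centroid_t1; c2 <- region$centroid_t2
  sup <- .region_support(spec, region)
  g1 <- spec$t1_grid; g2 <- spec$t2_grid
  new1 <- c1 + (sup$t1 - c1) * (1 + s1)
  new2 <- c2 + (sup$t2 - c2) * (1 + s2)
  if (min(new1) < g1[1] || max(new1) > g1[length(g1)] ||
      min(new2) < g2[1] || max(new2) > g2[length(g2)]) {
    stop_boundary("stretch moves peak support outside the grid")
  }
  parts <- .split_peak(spec, region)
  q1 <- c1 + (g1 - c1) / (1 + s1)
  q2 <- c2 + (g2 - c2) / (1 + s2)
  stretched <- .interp_peak(parts$peak, g1, g2, q1, q2)
  .rebuild_spectrum(spec, parts$base, stretched, region$total_intensity)
}

## One randomized shift+stretch pass over every detected peak.
## Boundary-violating draws are redrawn (up to `max_attempts` per peak).
.augment_once <- function(spec, params, detect_args, max_attempts = 100L) {
  regions <- do.call(detect_peaks, c(list(spec), detect_args))
  applied <- list()
  out <- spec
  for (k in seq_along(regions)) {
    ## re-detect so later peaks see the current spectrum state
    regs <- do.call(detect_peaks, c(list(out), detect_args))
    if (k > length(regs)) break
    region <- regs[[k]]
    done <- FALSE
    for (att in seq_len(max_attempts)) {
      dt1 <- stats::rnorm(1, 0, params$shift_std_t1)
      dt2 <- stats::rnorm(1, 0, params$shift_std_t2)
      s1 <- stats::rnorm(1, 0, params$stretch_std)
      s2 <- stats::rnorm(1, 0, params$stretch_std)
      cand <- tryCatch({
        tmp <- stretch_peak(out, region, s1, s2)
        regs2 <- do.call(detect_peaks, c(list(tmp), detect_args))
        if (k > length(regs2)) region2 <- region else region2 <- regs2[[k]]
        shift_peak(tmp, region2, dt1, dt2)
      }, relaxcell_boundary_error = function(e) NULL)
      if (!is.null(cand)) {
        out <- cand
        applied[[k]] <- c(dt1 = dt1, dt2 = dt2, s1 = s1, s2 = s2,
                          centroid_t1 = region$centroid_t1,
                          centroid_t2 = region$centroid_t2)
        done <- TRUE
        break
      }
    }
    if (!done) stop_arg("no in-bounds augmentation draw found in ",
                        max_attempts, " attempts")
  }
  list(spectrum = out, applied = applied)
}

#' Randomly augment one spectrum
#'
#' Runs the shift/stretch augmentation `factor` times on the input
#' spectrum.  Each iteration draws, per detected peak, independent
#' shifts `~ Normal(0, shift_std)` per dimension and stretches
#' `~ Normal(0, stretch_std)`, applies them in linear coordinates, and
#' conserves each peak's total intensity.  Draws whose result would
#' leave the grid are redrawn.  Deterministic given the seed.
#'
#' @param spec a [spectrum2d()] with at least one detectable peak.
#' @param params an [augmentation_params()].
#' @param detect_args list of arguments for [detect_peaks()].
#' @return List of [spectrum2d()]: the flagged original first (when
#'   `keep_original`), then the `factor` augmented copies.  Each
#'   spectrum's metadata carries `augmented`, `parent_id`, `draw` and
#'   the applied per-peak parameters.
#' @export
augment_spectrum <- function(spec, params, detect_args = list()) {
  stopifnot(inherits(spec, "spectrum2d"),
            inherits(params, "augmentation_params"))
  parent <- spec$metadata$sample_id %||% "sample"
  out <- list()
  if (params$keep_original) {
    orig <- spec
    orig$metadata$augmented <- FALSE
    orig$metadata$parent_id <- parent
    orig$metadata$draw <- 0L
    out[[length(out) + 1L]] <- orig
  }
  if (params$factor > 0) {
    draws <- with_seed(params$seed, {
      lapply(seq_len(params$factor), function(k) {
        .augment_once(spec, params, detect_args)
      })
    })
    for (k in seq_along(draws)) {
      aug <- draws[[k]]$spectrum
      aug$metadata$augmented <- TRUE
      aug$metadata$parent_id <- parent
      aug$metadata$draw <- k
      aug$metadata$sample_id <- sprintf("%s_aug%02d", parent, k)
      aug$metadata$applied <- draws[[k]]$applied
      out[[length(out) + 1L]] <- aug
    }
  }
  out
}

#' Augment a cohort of spectra
#'
#' Applies [augment_spectrum()] to every spectrum with an independent
#' seed derived from the root seed and the sample id, optionally with
#' class-specific parameter overrides, and returns the augmented cohort
#' together with a lineage manifest.
#'
#' @param spectra list of [spectrum2d()] objects.
#' @param params default [augmentation_params()].
#' @param class_overrides named list mapping a `class_label` to its own
#'   `augmentation_params`.
#' @param detect_args list of arguments for [detect_peaks()].
#' @return List with `spectra` (flat list, originals flagged) and
#'   `manifest` (`data.frame`: sample_id, parent_id, class_label, draw,
#'   is_original, and the applied cell-peak shift/stretch values).
#' @export
augment_dataset <- function(spectra, params = augmentation_params(),
                            class_overrides = NULL, detect_args = list()) {
  out <- list()
  rows <- list()
  for (spec in spectra) {
    cls <- spec$metadata$class_label %||% NA_character_
    p <- params
    if (!is.null(class_overrides) && !is.na(cls) && cls %in% names(class_overrides)) {
      p <- class_overrides[[cls]]
    }
    p$seed <- derive_seed(params$seed, "augment",
                          spec$metadata$sample_id %||% "sample")
    fam <- augment_spectrum(spec, p, detect_args = detect_args)
    for (a in fam) {
      is_orig <- !isTRUE(a$metadata$augmented)
      ## lineage row records the draw applied to the dominant cell peak
      ap <- if (is_orig) NULL else {
        valid <- Filter(Negate(is.null), a$metadata$applied)
        if (length(valid)) valid[[1]] else NULL
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = a$metadata$sample_id %||% NA_character_,
        parent_id = a$metadata$parent_id,
        class_label = cls,
        draw = a$metadata$draw,
        is_original = is_orig,
        shift_t1 = if (is.null(ap)) NA_real_ else ap[["dt1"]],
        shift_t2 = if (is.null(ap)) NA_real_ else ap[["dt2"]],
        stretch_t1 = if (is.null(ap)) NA_real_ else ap[["s1"]],
        stretch_t2 = if (is.null(ap)) NA_real_ else ap[["s2"]])
      out[[length(out) + 1L]] <- a
    }
  }
  list(spectra = out, manifest = do.call(rbind, rows))
}
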