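test_that("peak detection finds the expected blobs and filters by size", {
  grid <- spectrum_grid(100)
  zero <- spectrum2d(grid$t1, grid$t2, matrix(0, 100, 100))
  expect_identical(detect_peaks(zero), list())
  # cell + media blobs -> two peaks, sorted by intensity
  two <- blob_spectrum(rbind(c(0.5, 0.05), c(2.5, 2.0)), amps = c(1, 2))
  pk <- detect_peaks(two)
  expect_length(pk, 2)
  expect_gt(pk[[1]]$total_intensity, pk[[2]]$total_intensity)
  # a one-cell speck is removed by the area filter
  speck <- two
  speck$intensity[1, 1] <- max(speck$intensity) * 0.5
  expect_length(detect_peaks(speck, min_area = 4), 2)
  expect_error(detect_peaks(two, threshold_frac = 0), "threshold")
})

test_that("raising the threshold never increases the peak count", {
  spec <- blob_spectrum(rbind(c(0.4, 0.03), c(0.9, 0.15), c(2.5, 2.0)),
                        amps = c(1, 0.4, 1.5))
  counts <- vapply(c(0.02, 0.05, 0.1, 0.3, 0.6, 0.9),
                   function(th) length(detect_peaks(spec, threshold_frac = th)),
                   0L)
  expect_false(is.unsorted(rev(counts)))
})

test_that("a differentiated-MSC spectrum resolves three peaks", {
  # nominal (unjittered) positions: water cell peak, lipid peak, media peak
  lib <- phenotype_library(cell_jitter = 0)
  p <- acquisition_protocol(noise_sigma = 0)
  td <- simulate_sample(lib$MSC_diff, p, seed = 3)
  spec <- suppressWarnings(reconstruct_spectrum(td, grid = spectrum_grid(100),
                                                alpha = 1e-3, max_iter = 8000))
  pk <- tag_peaks(detect_peaks(spec))
  expect_length(pk, 3)
  expect_setequal(vapply(pk, `[[`, "", "tag"), c("cell", "media", "lipid"))
  # the lipid tag goes to the shortest-T1 cell-window peak
  lip <- Filter(function(r) r$tag == "lipid", pk)[[1]]
  cel <- Filter(function(r) r$tag == "cell", pk)[[1]]
  expect_lt(lip$centroid_t1, cel$centroid_t1)
})

test_that("peak tagging follows the media window rule", {
  media <- blob_spectrum(rbind(c(2.5, 2.0)))
  tg <- tag_peaks(detect_peaks(media))
  expect_identical(tg[[1]]$tag, "media")
  cell <- blob_spectrum(rbind(c(0.6, 0.08)))
  expect_identical(tag_peaks(detect_peaks(cell))[[1]]$tag, "cell")
  expect_identical(tag_peaks(list()), list())
})

test_that("weighted centroids match brute-force oracles and scale-invariance", {
  grid <- spectrum_grid(100)
  # single lit cell
  X <- matrix(0, 100, 100); X[40, 30] <- 2
  sp <- spectrum2d(grid$t1, grid$t2, X)
  r <- list(cells = which(X > 0))
  expect_equal(weighted_centroid(r, sp),
               c(t1 = grid$t1[40], t2 = grid$t2[30]))
  # two equal cells average their coordinates
  X2 <- matrix(0, 100, 100); X2[40, 30] <- 1; X2[60, 30] <- 1
  sp2 <- spectrum2d(grid$t1, grid$t2, X2)
  r2 <- list(cells = which(X2 > 0))
  expect_equal(unname(weighted_centroid(r2, sp2)[1]),
               (grid$t1[40] + grid$t1[60]) / 2)
  # Gaussian blob on a node: centroid within half a cell of the node
  blob <- blob_spectrum(rbind(c(0.5, 0.05)))
  pk <- detect_peaks(blob)[[1]]
  i0 <- which.min(abs(grid$t1 - 0.5))
  half1 <- (grid$t1[i0 + 1] - grid$t1[i0 - 1]) / 4
  expect_lt(abs(pk$centroid_t1 - grid$t1[i0]), half1)
  # exact invariance under global intensity scaling
  blob7 <- spectrum2d(grid$t1, grid$t2, 7 * blob$intensity)
  expect_equal(weighted_centroid(pk, blob7), weighted_centroid(pk, blob),
               tolerance = 1e-14)
  rzero <- list(cells = 1:3)
  expect_error(weighted_centroid(rzero, spectrum2d(grid$t1, grid$t2,
                                                   matrix(0, 100, 100))),
               "zero total intensity")
})

test_that("cell-window cropping uses the published bounds and is idempotent", {
  spec <- blob_spectrum(rbind(c(0.5, 0.05), c(2.5, 2.0)))
  cr <- crop_to_cell_window(spec)
  expect_true(all(cr$t1_grid <= 3.0079))
  expect_true(all(cr$t2_grid <= 0.4062))
  expect_identical(unname(cr$metadata$crop_window), c(3.0079, 0.4062))
  # the media peak at (2.5 s, 2.0 s) is excluded by the T2 bound
  expect_length(detect_peaks(cr), 1)
  expect_lt(detect_peaks(cr)[[1]]$centroid_t1, 1)
  # idempotence and whole-grid identity
  cr2 <- crop_to_cell_window(cr)
  expect_identical(cr2$intensity, cr$intensity)
  all_of_it <- crop_to_cell_window(spec, t1_max = Inf, t2_max = Inf)
  expect_identical(all_of_it$intensity, spec$intensity)
  expect_error(crop_to_cell_window(spec, t1_max = 1e-9, t2_max = 1e-9),
               "overlap")
})

test_that("centroid tables pick the strongest cell peak and log exclusions", {
  s1 <- blob_spectrum(rbind(c(0.5, 0.05), c(2.5, 2.0)), amps = c(1, 2),
                      id = "cells")
  s1$metadata$class_label <- "CHO"
  # two cell-window peaks: the more intense one is used
  s2 <- blob_spectrum(rbind(c(0.4, 0.03), c(0.9, 0.2), c(2.5, 2.0)),
                      amps = c(0.5, 1, 2), id = "twocell")
  s2$metadata$class_label <- "MSC_diff"
  media <- blob_spectrum(rbind(c(2.5, 2.0)), id = "media_only")
  media$metadata$class_label <- "media_only"
  tab <- centroid_table(list(s1, s2, media))
  expect_identical(nrow(tab), 2L)
  expect_identical(attr(tab, "exclusions")$sample_id, "media_only")
  got <- tab[tab$sample_id == "twocell", ]
  expect_lt(abs(got$t1 - 0.9), 0.1)  # stronger of the two cell peaks
  expect_identical(nrow(centroid_table(list())), 0L)
})

test_that("synthetic phenotype centroids cluster by class", {
  cen <- fixture_ten_line_centroids()
  expect_identical(nrow(cen), 80L)
  # silhouette > 0 in log coordinates: classes separate more than they spread
  X <- log10(as.matrix(cen[, c("t1", "t2")]))
  d <- as.matrix(dist(X))
  sil <- vapply(seq_len(nrow(X)), function(i) {
    own <- cen$class_label == cen$class_label[i]
    a <- mean(d[i, own & seq_len(nrow(X)) != i])
    b <- min(vapply(setdiff(unique(cen$class_label), cen$class_label[i]),
                    function(cl) mean(d[i, cen$class_label == cl]), 0))
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0)
})
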