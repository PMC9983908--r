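test_that("zero-parameter operators are the identity", {
  sp <- blob_spectrum(rbind(c(0.5, 0.05)))
  r <- detect_peaks(sp)[[1]]
  expect_lt(max(abs(shift_peak(sp, r, 0, 0)$intensity - sp$intensity)), 1e-9)
  expect_lt(max(abs(stretch_peak(sp, r, 0, 0)$intensity - sp$intensity)), 1e-9)
})

test_that("both operators conserve total intensity", {
  sp <- blob_spectrum(rbind(c(0.5, 0.05), c(2.5, 2.0)), amps = c(1, 1.5))
  tot <- sum(sp$intensity)
  pks <- detect_peaks(sp)
  for (draw in 1:5) {
    withr::with_seed(draw, {
      dt1 <- stats::rnorm(1, 0, 0.02)
      dt2 <- stats::rnorm(1, 0, 0.005)
      s1 <- stats::rnorm(1, 0, 0.05)
    })
    sh <- shift_peak(sp, pks[[2]], dt1, dt2)
    expect_lt(abs(sum(sh$intensity) - tot) / tot, 1e-6)
    st <- stretch_peak(sp, pks[[2]], s1, s1)
    expect_lt(abs(sum(st$intensity) - tot) / tot, 1e-6)
  }
})

test_that("a shift moves the centroid by the requested amount", {
  sp <- blob_spectrum(rbind(c(0.5, 0.05)))
  r <- detect_peaks(sp)[[1]]
  sh <- shift_peak(sp, r, 0.1, 0)
  r2 <- detect_peaks(sh)[[1]]
  i0 <- which.min(abs(sp$t1_grid - 0.6))
  half_cell <- (sp$t1_grid[i0 + 1] - sp$t1_grid[i0]) / 2
  expect_lt(abs((r2$centroid_t1 - r$centroid_t1) - 0.1), half_cell)
  expect_lt(abs(r2$centroid_t2 - r$centroid_t2), 1e-3)
})

test_that("a stretch scales the peak's second central moment", {
  sp <- blob_spectrum(rbind(c(0.5, 0.05)))
  r <- detect_peaks(sp)[[1]]
  st <- stretch_peak(sp, r, 0.1, 0)
  # integral-weighted T1 variance scales by (1 + s)^2
  expect_equal(t1_second_moment(st) / t1_second_moment(sp), 1.1^2,
               tolerance = 0.02)
})

test_that("out-of-grid transformations raise boundary errors", {
  sp <- blob_spectrum(rbind(c(10, 0.05)))
  r <- detect_peaks(sp)[[1]]
  expect_error(shift_peak(sp, r, 10, 0), class = "relaxcell_boundary_error")
  expect_error(stretch_peak(sp, r, 5, 0), class = "relaxcell_boundary_error")
  expect_error(stretch_peak(sp, r, -1, 0), "positive")
})

test_that("augment_spectrum produces factor + original deterministic copies", {
  sp <- blob_spectrum(rbind(c(0.5, 0.05), c(2.5, 2.0)), id = "parent")
  prm <- augmentation_params(shift_std_t1 = 0.003, stretch_std = 0.01,
                             factor = 5L, seed = 42)
  fam <- augment_spectrum(sp, prm)
  expect_length(fam, 6)
  flags <- vapply(fam, function(s) isTRUE(s$metadata$augmented), TRUE)
  expect_identical(sum(!flags), 1L)
  expect_identical(fam[[1]]$metadata$draw, 0L)
  expect_identical(fam[[2]]$metadata$parent_id, "parent")
  # factor 0 keeps only the original
  expect_length(augment_spectrum(sp, augmentation_params(factor = 0L)), 1)
  # bit-identical under the same seed, different under another
  fam2 <- augment_spectrum(sp, prm)
  expect_identical(lapply(fam, `[[`, "intensity"), lapply(fam2, `[[`, "intensity"))
  prm2 <- prm; prm2$seed <- 43L
  fam3 <- augment_spectrum(sp, prm2)
  expect_false(identical(fam[[2]]$intensity, fam3[[2]]$intensity))
})

test_that("applied augmentation draws are unbiased with the configured std", {
  sp <- blob_spectrum(rbind(c(0.5, 0.05)), n = 48L)
  prm <- augmentation_params(shift_std_t1 = 0.004, shift_std_t2 = 0.002,
                             stretch_std = 0.02, factor = 1000L, seed = 7,
                             keep_original = FALSE)
  fam <- augment_spectrum(sp, prm)
  ap <- t(vapply(fam, function(s) s$metadata$applied[[1]][1:4], numeric(4)))
  for (col in 1:4) {
    std <- c(0.004, 0.002, 0.02, 0.02)[col]
    expect_lt(abs(mean(ap[, col])), 3 * std / sqrt(1000))
    expect_lt(abs(stats::sd(ap[, col]) - std) / std, 0.10)
  }
})

test_that("dataset augmentation keeps lineage and honours presets", {
  specs <- lapply(1:15, function(i) {
    s <- blob_spectrum(rbind(c(0.5 * (1 + 0.02 * i), 0.05)),
                       id = sprintf("s%02d", i))
    s$metadata$class_label <- if (i <= 8) "undiff" else "diff"
    s
  })
  res <- augment_dataset(specs, augmentation_preset("msc", factor = 5L, seed = 9))
  expect_length(res$spectra, 90)           # 15 * (5 + 1)
  man <- res$manifest
  expect_identical(nrow(man), 90L)
  expect_true(all(man$parent_id %in% man$sample_id[man$is_original]))
  # recorded shift equals the achieved centroid displacement (one cell)
  aug_rows <- which(!man$is_original)
  for (i in aug_rows[1:5]) {
    s <- res$spectra[[i]]
    parent <- res$spectra[[which(man$sample_id == man$parent_id[i] &
                                 man$is_original)]]
    d1 <- detect_peaks(s)[[1]]$centroid_t1 -
      detect_peaks(parent)[[1]]$centroid_t1
    cell <- parent$t1_grid[2] / parent$t1_grid[1]
    c0 <- detect_peaks(parent)[[1]]$centroid_t1
    expect_lt(abs(d1 - man$shift_t1[i]), c0 * (cell - 1))
  }
  # presets carry the published parameter choices
  expect_identical(augmentation_preset("msc")$shift_std_t1, 0.005)
  expect_identical(augmentation_preset("cell_line")$shift_std_t1, 0.001)
  expect_identical(augmentation_preset("msc")$stretch_std, 0.01)
  expect_identical(augmentation_preset("msc")$factor, 5L)
})
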