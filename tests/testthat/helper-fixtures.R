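# Shared fixtures, generated in code. Expensive cohorts are built once
# per test session and memoised in this environment.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small noiseless protocol for cheap simulations
quiet_protocol <- function(n_echoes = 5000L, noise_sigma = 0) {
  acquisition_protocol(n_echoes = n_echoes, noise_sigma = noise_sigma)
}

# a Gaussian blob spectrum (in grid-index space) on the default log grid
blob_spectrum <- function(centers, sigma = 2, amps = rep(1, nrow(centers)),
                          n = 100L, id = "blob") {
  grid <- spectrum_grid(n)
  X <- matrix(0, n, n)
  for (k in seq_len(nrow(centers))) {
    i0 <- which.min(abs(grid$t1 - centers[k, 1]))
    j0 <- which.min(abs(grid$t2 - centers[k, 2]))
    X <- X + amps[k] * outer(seq_len(n), seq_len(n), function(i, j) {
      exp(-((i - i0)^2 + (j - j0)^2) / (2 * sigma^2))
    })
  }
  spectrum2d(grid$t1, grid$t2, X, metadata = list(sample_id = id))
}

# integral-weighted second central moment of a spectrum along T1
t1_second_moment <- function(spec) {
  n1 <- length(spec$t1_grid); n2 <- length(spec$t2_grid)
  d1 <- c(diff(spec$t1_grid), diff(spec$t1_grid)[n1 - 1])
  d2 <- c(diff(spec$t2_grid), diff(spec$t2_grid)[n2 - 1])
  W <- spec$intensity * outer(d1, d2)
  t1m <- matrix(spec$t1_grid, n1, n2)
  c1 <- sum(W * t1m) / sum(W)
  sum(W * (t1m - c1)^2) / sum(W)
}

# reconstructed spectra for a two-line, clearly separable cohort
fixture_two_line_spectra <- function() {
  fixture("two_line", function() {
    man <- cohort_manifest(c("CHO", "K562"), c(15L, 15L), seed = 301)
    cohort_spectra(man, grid_n = 100L, alpha = 1e-3, max_iter = 3000L)
  })
}

# reconstructed MSC cohort (8 undifferentiated + 7 differentiated)
fixture_msc_spectra <- function() {
  fixture("msc", function() {
    man <- cohort_manifest(c("MSC_undiff", "MSC_diff"), c(8L, 7L), seed = 411)
    cohort_spectra(man, grid_n = 100L, alpha = 1e-3, max_iter = 8000L)
  })
}

# full 10-line reduced cohort and its centroid table
fixture_ten_line_centroids <- function() {
  fixture("ten_line", function() {
    lines <- c("A549", "C2C12", "CHO", "HEK293T", "HeLa",
               "K562", "L929", "MDA231", "THP1", "Vero")
    man <- cohort_manifest(lines, rep(8L, 10), seed = 509)
    centroid_table(cohort_spectra(man, grid_n = 100L, alpha = 1e-3,
                                  max_iter = 3000L))
  })
}

# well-separated two-class blob images for direct network tests
blob_image_cohort <- function(n = 60L, size = 32L, seed = 17L) {
  withr::with_seed(seed, {
    imgs <- array(0, c(size, size, n))
    lab <- character(n)
    for (i in seq_len(n)) {
      cl <- if (i %% 2L) "A" else "B"
      cx <- (if (cl == "A") 10 else 21) + stats::rnorm(1)
      cy <- (if (cl == "A") 12 else 19) + stats::rnorm(1)
      g <- outer(seq_len(size), seq_len(size),
                 function(x, y) exp(-((x - cx)^2 + (y - cy)^2) / 8))
      imgs[, , i] <- g / max(g)
      lab[i] <- cl
    }
    list(images = imgs,
         meta = data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                           class_label = lab,
                           parent_id = sprintf("s%03d", seq_len(n))))
  })
}
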