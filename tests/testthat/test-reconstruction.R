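noiseless_sample <- function(t1, t2, amp = 1, seed = 1) {
  p <- acquisition_protocol(noise_sigma = 0)
  ph <- relaxation_phenotype("x", list(relaxation_component(t1, t2, amp)))
  simulate_sample(ph, p, seed = seed)
}

test_that("echo collapse averages intra-echo points", {
  ti <- c(0.1, 1); et <- c(0.003, 0.006, 0.009)
  amp <- matrix(1:6, 2, 3)
  td <- time_domain_data(ti, et, amp)
  expect_equal(collapse_echo_points(td)$amplitudes, amp)  # already collapsed
  # raw tensor with symmetric +/- eps perturbation collapses to the mean
  raw <- array(rep(amp, 2), dim = c(2, 3, 2))
  raw[, , 1] <- raw[, , 1] + 0.25
  raw[, , 2] <- raw[, , 2] - 0.25
  td2 <- time_domain_data(ti, et, amp, raw = raw)
  expect_equal(collapse_echo_points(td2)$amplitudes, amp)
})

test_that("log re-gridding reaches 256 bins and preserves exponentials", {
  td <- noiseless_sample(0.8, 0.5)
  ser <- collapse_echo_points(td)
  rg <- regrid_log_t2(ser, 256)
  expect_identical(ncol(rg$amplitudes), 256L)
  expect_equal(rg$echo_times[1], ser$echo_times[1])
  expect_equal(rg$echo_times[256], ser$echo_times[5000])
  # constant signal stays constant
  cser <- echo_series(c(1, 2), ser$echo_times,
                      matrix(3, 2, 5000))
  expect_true(all(abs(regrid_log_t2(cser, 256)$amplitudes - 3) < 1e-12))
  # pure exponential: bin means track the bin-center values
  # (bound verified against direct evaluation; bin-averaging bias is
  # below 5e-3 for T2 = 0.5 s on this echo train)
  row <- rg$amplitudes[32, ]
  truth <- (1 - 2 * exp(-15 / 0.8)) * exp(-rg$echo_times / 0.5)
  expect_lt(max(abs(row - truth)), 5e-3)
  expect_error(regrid_log_t2(echo_series(c(1, 2), et <- c(0.1, 0.2),
                                         matrix(0, 2, 2)), 256), "exceeds")
})

test_that("normalization is a max-1 rescale with recoverable scale", {
  ser <- collapse_echo_points(noiseless_sample(0.5, 0.1, amp = 7))
  ns <- normalize_series(ser)
  expect_equal(max(abs(ns$amplitudes)), 1)
  expect_equal(ns$metadata$norm_scale * ns$amplitudes, ser$amplitudes)
  # scale invariance of the normalized result
  ser2 <- ser; ser2$amplitudes <- ser$amplitudes / 7
  expect_equal(normalize_series(ser2)$amplitudes, ns$amplitudes)
  zero <- echo_series(c(1, 2), c(0.1, 0.2), matrix(0, 2, 2))
  expect_error(normalize_series(zero), "all-zero")
})

test_that("PCA denoising truncates exactly and recovers low-rank data", {
  p <- acquisition_protocol(noise_sigma = 0)
  ph <- relaxation_phenotype("x", list(relaxation_component(0.5, 0.05, 1),
                                       relaxation_component(2.5, 2.0, 1.2)))
  ser <- regrid_log_t2(collapse_echo_points(simulate_sample(ph, p, seed = 1)), 256)
  # separable 2-component forward model has rank 2
  den <- pca_denoise(ser, rank = 2)
  expect_lt(max(abs(den$amplitudes - ser$amplitudes)) / max(abs(ser$amplitudes)),
            1e-10)
  # full rank is the identity
  full <- pca_denoise(ser, rank = 32)
  expect_equal(full$amplitudes, ser$amplitudes, tolerance = 1e-12)
  expect_error(pca_denoise(ser, rank = 0), "rank")
  expect_error(pca_denoise(ser, rank = 33), "rank")
})

test_that("T1 orientation fixes global polarity and flags the flip", {
  ser <- regrid_log_t2(collapse_echo_points(noiseless_sample(0.8, 0.1)), 256)
  ok <- orient_t1(ser)
  expect_false(ok$metadata$t1_flipped)
  expect_equal(ok$amplitudes, ser$amplitudes)
  neg <- ser; neg$amplitudes <- -ser$amplitudes
  fixed <- orient_t1(neg)
  expect_true(fixed$metadata$t1_flipped)
  expect_equal(fixed$amplitudes, ser$amplitudes)
  # rows below the inversion null stay negative at early echoes,
  # as the IR kernel prescribes
  below <- which(ser$ti_vector < 0.8 * log(2))
  expect_true(all(ok$amplitudes[below, 1] < 0))
})

test_that("kernel matrices evaluate the IR and CPMG closed forms", {
  grid <- spectrum_grid(50)
  p <- acquisition_protocol(n_echoes = 100L)
  ker <- build_kernels(p, grid$t1, grid$t2)
  expect_identical(dim(ker$K1), c(32L, 50L))
  expect_identical(dim(ker$K2), c(100L, 50L))
  ker2 <- build_kernels(p, c(1, 2), c(1e6, 2e6))
  expect_equal(ker2$K1[32, 1], 1 - 2 * exp(-15), tolerance = 1e-12)
  # K2 -> 1 in the long-T2 limit
  expect_true(all(abs(ker2$K2[1, ] - 1) < 1e-6))
  # K1 entry vanishes where TI = T1 ln 2 (first TI is 5 ms)
  ti_null <- build_kernels(p, c(0.005 / log(2), 1), c(1, 2))
  expect_lt(abs(ti_null$K1[1, 1]), 1e-12)
  expect_error(build_kernels(p, c(2, 1), c(1, 2)), "increasing")
})

test_that("the inverse Laplace transform recovers on-grid components", {
  grid <- spectrum_grid(100)
  # all-zero data give the all-zero spectrum
  zero <- echo_series(log_spaced_inversion_times(32, 0.005, 15),
                      log_seq(0.003, 15, 256), matrix(0, 32, 256))
  spec0 <- ilt2d(zero, grid$t1, grid$t2, alpha = 1e-3)
  expect_true(all(spec0$intensity == 0))
  # noiseless single component placed exactly on the grid
  i0 <- 60L; j0 <- 45L
  td <- noiseless_sample(grid$t1[i0], grid$t2[j0])
  ser <- orient_t1(normalize_series(regrid_log_t2(collapse_echo_points(td), 256)))
  spec <- suppressWarnings(ilt2d(ser, grid$t1, grid$t2, alpha = 1e-6,
                                 max_iter = 4000))
  expect_true(all(spec$intensity >= 0))
  top <- detect_peaks(spec)[[1]]
  expect_lte(abs(top$centroid_t1 - grid$t1[i0]), grid$t1[i0 + 1] - grid$t1[i0])
  expect_lte(abs(top$centroid_t2 - grid$t2[j0]), grid$t2[j0 + 1] - grid$t2[j0])
  # forward projection reproduces the data
  ker <- build_kernels(ser, grid$t1, grid$t2)
  resid <- sqrt(sum((ser$amplitudes - ker$K1 %*% spec$intensity %*% t(ker$K2))^2))
  expect_lt(resid / sqrt(sum(ser$amplitudes^2)), 0.02)
  expect_equal(spec$metadata$residual_norm, resid, tolerance = 1e-8)
})

test_that("SVD compression leaves the objective unchanged on a toy problem", {
  # 20 x 40 problem, solved with and without kernel compression
  ti <- log_seq(0.005, 15, 20)
  et <- log_seq(0.003, 10, 40)
  g1 <- log_seq(0.01, 10, 15)
  g2 <- log_seq(0.01, 5, 15)
  K1 <- 1 - 2 * exp(-outer(ti, g1, "/"))
  K2 <- exp(-outer(et, g2, "/"))
  Ftrue <- matrix(0, 15, 15); Ftrue[7, 8] <- 1
  S <- K1 %*% Ftrue %*% t(K2)
  ser <- echo_series(ti, et, S)
  alpha <- 1e-4
  obj <- function(spec) {
    sum((S - K1 %*% spec$intensity %*% t(K2))^2) + alpha * sum(spec$intensity^2)
  }
  full <- suppressWarnings(ilt2d(ser, g1, g2, alpha, r1 = Inf, r2 = Inf,
                                 max_iter = 20000, tol = 1e-12))
  comp <- suppressWarnings(ilt2d(ser, g1, g2, alpha, r1 = 20, r2 = 40,
                                 max_iter = 20000, tol = 1e-12))
  expect_lt(abs(obj(full) - obj(comp)) / obj(full), 1e-8)
})

test_that("solver error mode carries the last iterate", {
  ser <- orient_t1(normalize_series(regrid_log_t2(collapse_echo_points(
    noiseless_sample(0.5, 0.05)), 256)))
  grid <- spectrum_grid(60)
  err <- tryCatch(
    ilt2d(ser, grid$t1, grid$t2, alpha = 1e-8, max_iter = 5L,
          on_nonconverge = "error"),
    relaxcell_solver_error = function(e) e)
  expect_s3_class(err, "relaxcell_solver_error")
  expect_s3_class(err$spectrum, "spectrum2d")
})

test_that("discrepancy-principle alpha grows with the noise level", {
  grid <- spectrum_grid(60)
  base <- regrid_log_t2(collapse_echo_points(noiseless_sample(0.5, 0.05)), 256)
  base <- orient_t1(normalize_series(base))
  alphas_out <- vapply(c(0.002, 0.01, 0.05), function(sig) {
    noisy <- base
    noisy$amplitudes <- noisy$amplitudes +
      withr::with_seed(7, matrix(stats::rnorm(length(base$amplitudes), 0, sig),
                                 nrow(base$amplitudes)))
    choose_alpha(noisy, grid$t1, grid$t2, noise_sigma = sig, max_iter = 2000)
  }, 0)
  expect_false(is.unsorted(alphas_out))
  # residual of the chosen alpha sits below the discrepancy bound
  sig <- 0.01
  noisy <- base
  noisy$amplitudes <- noisy$amplitudes +
    withr::with_seed(8, matrix(stats::rnorm(length(base$amplitudes), 0, sig),
                               nrow(base$amplitudes)))
  a <- choose_alpha(noisy, grid$t1, grid$t2, noise_sigma = sig, max_iter = 2000)
  spec <- suppressWarnings(ilt2d(noisy, grid$t1, grid$t2, a, max_iter = 2000))
  expect_lte(spec$metadata$residual_norm,
             1.1 * sig * sqrt(length(noisy$amplitudes)))
  # zero noise falls back to the configured default
  expect_equal(choose_alpha(base, grid$t1, grid$t2, noise_sigma = 0,
                            default_alpha = 0.123), 0.123)
})

test_that("pre-normalization amplitude linearity holds through the chain", {
  grid <- spectrum_grid(80)
  td1 <- noiseless_sample(0.5, 0.05, amp = 1)
  td2 <- noiseless_sample(0.5, 0.05, amp = 2)
  run <- function(td) {
    ser <- orient_t1(regrid_log_t2(collapse_echo_points(td), 256))
    suppressWarnings(ilt2d(ser, grid$t1, grid$t2, alpha = 1e-4, max_iter = 3000))
  }
  s1 <- run(td1); s2 <- run(td2)
  expect_equal(sum(s2$intensity) / sum(s1$intensity), 2, tolerance = 0.01)
  c1 <- detect_peaks(s1)[[1]]; c2 <- detect_peaks(s2)[[1]]
  # centroid unchanged within one (geometric) grid cell
  cell_ratio <- grid$t1[2] / grid$t1[1]
  expect_lte(abs(log(c1$centroid_t1 / c2$centroid_t1)), log(cell_ratio))
})
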