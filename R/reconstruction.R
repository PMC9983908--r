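#' Echo series: time-domain data on a (possibly re-gridded) echo axis
#'
#' @param ti_vector inversion times in seconds, strictly increasing.
#' @param echo_times echo times in seconds, strictly increasing.
#' @param amplitudes matrix `length(ti_vector) x length(echo_times)`.
#' @param metadata provenance list (sample id, normalization scale, ...).
#' @return Object of class `echo_series`.
#' @export
echo_series <- function(ti_vector, echo_times, amplitudes, metadata = list()) {
  if (is.unsorted(ti_vector, strictly = TRUE) ||
      is.unsorted(echo_times, strictly = TRUE)) {
    stop_arg("time axes must be strictly increasing")
  }
  stopifnot(nrow(amplitudes) == length(ti_vector),
            ncol(amplitudes) == length(echo_times))
  structure(list(ti_vector = ti_vector, echo_times = echo_times,
                 amplitudes = amplitudes, metadata = metadata),
            class = "echo_series")
}

#' Collapse intra-echo sampling points to per-echo amplitudes
#'
#' Each echo is acquired with several points; the per-echo amplitude is
#' their mean.  Data already collapsed pass through unchanged.
#'
#' @param raw a [time_domain_data()].
#' @return An [echo_series()] of dimension `n_inversions x n_echoes`.
#' @export
collapse_echo_points <- function(raw) {
  stopifnot(inherits(raw, "time_domain_data"))
  amp <- if (!is.null(raw$raw)) apply(raw$raw, c(1, 2), mean) else raw$amplitudes
  echo_series(raw$ti_vector, raw$echo_times, amp, metadata = raw$metadata)
}

#' Re-grid the echo axis to logarithmic spacing
#'
#' Maps the linearly sampled CPMG echo train onto `n_out` logarithmically
#' spaced bins between the first and last echo time.  Each output value
#' is the mean of the input echoes falling into its bin; bins that catch
#' no echo (possible at the short-time end) are filled by linear
#' interpolation in log-time.
#'
#' @param series an [echo_series()] with at least `n_out` echoes.
#' @param n_out number of output bins (default 256).
#' @return An [echo_series()] with `n_out` columns.
#' @export
regrid_log_t2 <- function(series, n_out = 256L) {
  stopifnot(inherits(series, "echo_series"))
  t_in <- series$echo_times
  m <- length(t_in)
  if (n_out > m) stop_arg("`n_out` exceeds the number of input echoes")
  centers <- log_seq(t_in[1], t_in[m], n_out)
  lc <- log(centers)
  edges <- c(lc[1] - (lc[2] - lc[1]) / 2,
             (lc[-1] + lc[-n_out]) / 2,
             lc[n_out] + (lc[n_out] - lc[n_out - 1]) / 2)
  bin <- findInterval(log(t_in), edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1L
  bin[bin > n_out] <- n_out
  sums <- rowsum(t(series$amplitudes), group = bin)       # filled bins x n_ti
  counts <- as.vector(table(factor(bin, levels = seq_len(n_out))))
  filled <- as.integer(rownames(sums))
  amp <- matrix(NA_real_, nrow(series$amplitudes), n_out)
  amp[, filled] <- t(sums) / rep(counts[filled], each = nrow(amp))
  empty <- which(counts == 0)
  if (length(empty)) {
    for (i in seq_len(nrow(amp))) {
      amp[i, empty] <- stats::approx(lc[filled], amp[i, filled],
                                     xout = lc[empty], rule = 2)$y
    }
  }
  md <- series$metadata
  md$regrid_bin_counts <- counts
  echo_series(series$ti_vector, centers, amp, metadata = md)
}

#' Normalize an echo series to unit maximum amplitude
#'
#' Divides by the maximum absolute amplitude; the scale is stored in
#' `metadata$norm_scale` so it can be undone.
#'
#' @param series an [echo_series()].
#' @return The normalized [echo_series()].
#' @export
normalize_series <- function(series) {
  stopifnot(inherits(series, "echo_series"))
  s <- max(abs(series$amplitudes))
  if (s == 0) stop_arg("cannot normalize an all-zero series")
  series$amplitudes <- series$amplitudes / s
  series$metadata$norm_scale <- s
  series
}

#' PCA noise reduction of an echo series
#'
#' Replaces the amplitude matrix by its best rank-`rank` approximation
#' (truncated SVD).  The IR-CPMG forward model is a sum of separable
#' terms, so noiseless data from a p-component sample has rank at most p;
#' discarding higher singular components removes mostly noise.
#'
#' @param series an [echo_series()].
#' @param rank truncation rank, `1 <= rank <= min(dim(amplitudes))`.
#' @return Denoised [echo_series()]; the norm of the discarded part is
#'   logged in `metadata$pca_residual`.
#' @export
pca_denoise <- function(series, rank = 8L) {
  stopifnot(inherits(series, "echo_series"))
  d <- dim(series$amplitudes)
  if (rank < 1 || rank > min(d)) stop_arg("`rank` must be in [1, ", min(d), "]")
  sv <- svd(series$amplitudes)
  r <- seq_len(rank)
  approx <- sv$u[, r, drop = FALSE] %*%
    (sv$d[r] * t(sv$v[, r, drop = FALSE]))
  series$metadata$pca_residual <-
    sqrt(max(0, sum(series$amplitudes^2) - sum(approx^2)))
  series$amplitudes <- approx
  series
}

#' Fix the longitudinal polarity convention
#'
#' Inversion-recovery rows below the null point are negative; the fit
#' assumes a convention in which the longest-TI (fully recovered) row is
#' positive.  `mode = "polarity"` (default) flips the global sign if the
#' longest-TI row is negative on average; `mode = "reverse"` additionally
#' supports the reading of "inverted in T1" as a reversal of the TI row
#' order (rarely wanted; the rows are re-sorted by TI so the container
#' invariant holds).
#'
#' @param series an [echo_series()].
#' @param mode `"polarity"` or `"reverse"`.
#' @return The oriented [echo_series()]; `metadata$t1_flipped` records
#'   whether a sign flip occurred.
#' @export
orient_t1 <- function(series, mode = c("polarity", "reverse")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "echo_series"))
  n <- length(series$ti_vector)
  flipped <- mean(series$amplitudes[n, ]) < 0
  if (flipped) series$amplitudes <- -series$amplitudes
  if (mode == "reverse") {
    series$amplitudes <- series$amplitudes[n:1, , drop = FALSE]
  }
  series$metadata$t1_flipped <- flipped
  series
}

#' Log-spaced T1/T2 reconstruction grids
#'
#' @param n points per dimension (default 300; analyses at reduced size
#'   pass e.g. 100).
#' @param t1_range,t2_range grid bounds in seconds.  Defaults span every
#'   peak the study system produces and the full TI range.
#' @return List with elements `t1` and `t2`.
#' @export
spectrum_grid <- function(n = 300L, t1_range = c(1e-3, 15), t2_range = c(1e-3, 5)) {
  list(t1 = log_seq(t1_range[1], t1_range[2], n),
       t2 = log_seq(t2_range[1], t2_range[2], n))
}

#' Build the IR and CPMG kernel matrices
#'
#' `K1[i, k] = 1 - 2 exp(-TI_i / T1_k)` and
#' `K2[j, l] = exp(-t_j / T2_l)`, so that noiseless data satisfy
#' `S = K1 F K2'` for the discrete T1/T2 distribution `F`.
#'
#' @param x an [echo_series()] or [acquisition_protocol()] supplying the
#'   TI and echo-time axes.
#' @param t1_grid,t2_grid strictly increasing grids in seconds.
#' @return List with matrices `K1` (`n_ti x length(t1_grid)`) and `K2`
#'   (`n_echo x length(t2_grid)`).
#' @export
build_kernels <- function(x, t1_grid, t2_grid) {
  if (inherits(x, "acquisition_protocol")) {
    ti <- protocol_ti(x); t <- protocol_echo_times(x)
  } else {
    ti <- x$ti_vector; t <- x$echo_times
  }
  if (is.unsorted(t1_grid, strictly = TRUE) ||
      is.unsorted(t2_grid, strictly = TRUE)) {
    stop_arg("grids must be strictly increasing")
  }
  list(K1 = 1 - 2 * exp(-outer(ti, t1_grid, "/")),
       K2 = exp(-outer(t, t2_grid, "/")))
}

#' 2D T1/T2 spectrum
#'
#' @param t1_grid,t2_grid log-spaced grids in seconds.
#' @param intensity nonnegative matrix `length(t1_grid) x length(t2_grid)`
#'   (rows index T1).
#' @param metadata list (sample id, alpha, residual norm, ...).
#' @return Object of class `spectrum2d`.
#' @export
spectrum2d <- function(t1_grid, t2_grid, intensity, metadata = list()) {
  stopifnot(nrow(intensity) == length(t1_grid),
            ncol(intensity) == length(t2_grid))
  if (any(intensity < 0)) stop_arg("spectrum intensity must be nonnegative")
  if (!all(is.finite(intensity))) stop_arg("spectrum intensity must be finite")
  structure(list(t1_grid = t1_grid, t2_grid = t2_grid,
                 intensity = intensity, metadata = metadata),
            class = "spectrum2d")
}

#' Regularized nonnegative 2D inverse Laplace transform
#'
#' Recovers the joint T1/T2 distribution `F >= 0` minimizing
#' `|| S - K1 F K2' ||_F^2 + alpha * || F ||_F^2`.
#' Both kernels are first compressed by truncated SVD (ranks `r1`, `r2`);
#' projecting the data onto the retained singular subspaces leaves the
#' objective unchanged up to a constant and shrinks the problem from
#' `n_ti x n_echo` to `r1 x r2`.  The compressed problem is solved by
#' FISTA (accelerated projected gradient) with projection onto the
#' nonnegative orthant.
#'
#' @param series oriented, normalized [echo_series()].
#' @param t1_grid,t2_grid reconstruction grids (see [spectrum_grid()]).
#' @param alpha Tikhonov weight (>= 0).
#' @param r1,r2 SVD truncation ranks; capped at the kernel dimensions.
#'   `Inf` disables compression.
#' @param max_iter iteration cap.
#' @param tol relative-change stopping tolerance.
#' @param on_nonconverge `"warn"` (default) or `"error"`; on error the
#'   condition carries the last iterate in its `spectrum` field.
#' @return A [spectrum2d()]; metadata records `alpha`, `residual_norm`
#'   (in the data's units, `||S - K1 F K2'||_F`), `iterations` and
#'   `converged`.
#' @export
ilt2d <- function(series, t1_grid, t2_grid, alpha = 1e-3,
                  r1 = 16L, r2 = 32L, max_iter = 5000L, tol = 1e-8,
                  on_nonconverge = c("warn", "error")) {
  on_nonconverge <- match.arg(on_nonconverge)
  stopifnot(inherits(series, "echo_series"))
  if (alpha < 0) stop_arg("`alpha` must be >= 0")
  S <- series$amplitudes
  ker <- build_kernels(series, t1_grid, t2_grid)
  r1 <- min(r1, dim(ker$K1))
  r2 <- min(r2, dim(ker$K2))
  sv1 <- svd(ker$K1, nu = r1, nv = r1)
  sv2 <- svd(ker$K2, nu = r2, nv = r2)
  K1c <- sv1$d[seq_len(r1)] * t(sv1$v)                 # r1 x n1
  K2c <- sv2$d[seq_len(r2)] * t(sv2$v)                 # r2 x n2
  Sc <- crossprod(sv1$u, S %*% sv2$u)                  # r1 x r2
  L <- 2 * (sv1$d[1]^2 * sv2$d[1]^2 + alpha)
  K1tK1 <- crossprod(K1c)
  K2tK2 <- crossprod(K2c)
  K1tS <- crossprod(K1c, Sc) %*% K2c                   # n1 x n2
  Fm <- matrix(0, length(t1_grid), length(t2_grid))
  Y <- Fm
  tk <- 1
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    grad <- 2 * (K1tK1 %*% Y %*% K2tK2 - K1tS + alpha * Y)
    Fn <- pmax(Y - grad / L, 0)
    step <- Fn - Fm
    ## adaptive restart: drop momentum when it opposes the descent
    if (sum(grad * step) > 0) tk <- 1
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Y <- Fn + ((tk - 1) / tn) * step
    rel <- sqrt(sum(step^2)) / max(sqrt(sum(Fn^2)), 1e-300)
    Fm <- Fn
    tk <- tn
    if (rel < tol) { converged <- TRUE; break }
  }
  resid <- sqrt(sum((S - ker$K1 %*% Fm %*% t(ker$K2))^2))
  md <- series$metadata
  md$alpha <- alpha
  md$residual_norm <- resid
  md$iterations <- iter
  md$converged <- converged
  spec <- spectrum2d(t1_grid, t2_grid, Fm, metadata = md)
  if (!converged) {
    msg <- sprintf("ilt2d did not reach tol %.1e in %d iterations (rel change %.2e)",
                   tol, max_iter, rel)
    if (on_nonconverge == "error") {
      cond <- structure(
        class = c("relaxcell_solver_error", "error", "condition"),
        list(message = msg, call = sys.call(), spectrum = spec)
      )
      stop(cond)
    }
    warning(msg, call. = FALSE)
  }
  spec
}

#' Pick the Tikhonov weight by the discrepancy principle
#'
#' Scans a log-spaced grid of candidate weights from large to small and
#' returns the largest `alpha` whose solution residual does not exceed
#' `(1 + tau)` times the expected noise norm
#' `noise_sigma * sqrt(n_ti * n_echo)`.  With `noise_sigma = 0` the
#' configured default is returned unchanged.
#'
#' @param series oriented, normalized [echo_series()].
#' @param t1_grid,t2_grid reconstruction grids.
#' @param noise_sigma per-entry noise std of `series$amplitudes` (on the
#'   same, typically max-normalized, scale).
#' @param tau discrepancy slack (default 0.1).
#' @param alphas candidate weights, descending after sorting.
#' @param default_alpha returned when `noise_sigma == 0`.
#' @param ... passed to [ilt2d()] (e.g. reduced `max_iter`).
#' @return The selected alpha.
#' @export
choose_alpha <- function(series, t1_grid, t2_grid, noise_sigma,
                         tau = 0.1, alphas = 10^seq(1, -6, length.out = 15),
                         default_alpha = 1e-3, ...) {
  if (noise_sigma < 0) stop_arg("`noise_sigma` must be >= 0")
  if (noise_sigma == 0) return(default_alpha)
  bound <- (1 + tau) * noise_sigma * sqrt(length(series$amplitudes))
  alphas <- sort(alphas, decreasing = TRUE)
  last <- alphas[length(alphas)]
  for (a in alphas) {
    spec <- suppressWarnings(ilt2d(series, t1_grid, t2_grid, alpha = a, ...))
    if (spec$metadata$residual_norm <= bound) return(a)
  }
  last
}

#' Full reconstruction chain: time domain to T1/T2 spectrum
#'
#' Applies, in order: intra-echo collapse, logarithmic T2 re-gridding,
#' max-normalization, PCA noise reduction, T1 polarity orientation, and
#' the regularized nonnegative 2D inverse Laplace transform.
#'
#' @param td a [time_domain_data()].
#' @param grid list with `t1` and `t2` grids (see [spectrum_grid()]).
#' @param n_t2 echo bins after re-gridding (default 256).
#' @param pca_rank truncation rank of the noise reduction (default 8).
#' @param alpha Tikhonov weight, or `"auto"` to apply [choose_alpha()]
#'   using the sample's known acquisition noise level.
#' @param ... passed to [ilt2d()].
#' @return A [spectrum2d()].
#' @export
reconstruct_spectrum <- function(td, grid = spectrum_grid(),
                                 n_t2 = 256L, pca_rank = 8L,
                                 alpha = 1e-3, ...) {
  series <- collapse_echo_points(td)
  series <- regrid_log_t2(series, n_out = n_t2)
  series <- normalize_series(series)
  series <- pca_denoise(series, rank = pca_rank)
  series <- orient_t1(series)
  if (identical(alpha, "auto")) {
    sig <- td$metadata$noise_sigma
    ppe <- td$metadata$points_per_echo
    if (is.null(sig) || is.null(ppe)) {
      stop_arg("alpha = \"auto\" needs noise metadata on the sample")
    }
    counts <- series$metadata$regrid_bin_counts
    scale <- series$metadata$norm_scale
    ## effective per-entry std after collapse, bin averaging and
    ## max-normalization (root mean over bins of per-bin variance)
    sig_eff <- sig / sqrt(ppe) / scale *
      sqrt(mean(1 / pmax(counts, 1)))
    alpha <- choose_alpha(series, grid$t1, grid$t2, noise_sigma = sig_eff,
                          max_iter = 500L)
  }
  ilt2d(series, grid$t1, grid$t2, alpha = alpha, ...)
}
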