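#' Acquisition protocol for an IR-CPMG relaxometry experiment
#'
#' Describes the timing of a combined inversion-recovery (IR) and
#' Carr-Purcell-Meiboom-Gill (CPMG) sequence: the inversion time TI is
#' stepped logarithmically over `n_inversions` values, and after each
#' inversion an echo train of `n_echoes` echoes spaced `echo_spacing_te`
#' seconds apart is recorded, each echo sampled with `points_per_echo`
#' points.
#'
#' @param n_inversions number of inversion times (TI steps).
#' @param ti_min,ti_max first and last inversion time in seconds.
#' @param n_echoes number of echoes in the CPMG train.
#' @param echo_spacing_te inter-echo time TE in seconds; echo j is
#'   acquired at time `j * TE` after excitation.
#' @param points_per_echo acquisition points per echo.
#' @param noise_sigma additive Gaussian noise standard deviation per raw
#'   acquisition point, relative to unit equilibrium magnetization.
#' @param seed integer seed for simulations using this protocol.
#'
#' @return An object of class `acquisition_protocol`.
#' @seealso [default_protocol()] for the scanner settings the synthetic
#'   cohort emulates.
#' @export
acquisition_protocol <- function(n_inversions = 32L,
                                 ti_min = 0.005,
                                 ti_max = 15.0,
                                 n_echoes = 5000L,
                                 echo_spacing_te = 0.003,
                                 points_per_echo = 40L,
                                 noise_sigma = 0.0632,
                                 seed = 1L) {
  if (!(ti_min > 0)) stop_arg("`ti_min` must be > 0")
  if (!(ti_max > ti_min)) stop_arg("`ti_max` must exceed `ti_min`")
  if (n_inversions < 2) stop_arg("`n_inversions` must be >= 2")
  if (n_echoes < 2) stop_arg("`n_echoes` must be >= 2")
  if (!(echo_spacing_te > 0)) stop_arg("`echo_spacing_te` must be > 0")
  if (points_per_echo < 1) stop_arg("`points_per_echo` must be >= 1")
  if (noise_sigma < 0) stop_arg("`noise_sigma` must be >= 0")
  structure(
    list(
      n_inversions = as.integer(n_inversions),
      ti_min = ti_min, ti_max = ti_max,
      ti_spacing = "logarithmic",
      n_echoes = as.integer(n_echoes),
      echo_spacing_te = echo_spacing_te,
      points_per_echo = as.integer(points_per_echo),
      noise_sigma = noise_sigma,
      seed = as.integer(seed)
    ),
    class = "acquisition_protocol"
  )
}

#' Default IR-CPMG protocol
#'
#' The benchtop scanner settings the synthetic data emulate: 32
#' logarithmically spaced inversion times from 5 ms to 15 s, a CPMG train
#' of 5000 echoes at TE = 3 ms, and 40 acquisition points per echo.  The
#' default noise level gives a signal-to-noise ratio of about 100 on the
#' first collapsed echo at full longitudinal recovery.
#'
#' @param ... overrides passed on to [acquisition_protocol()].
#' @return An `acquisition_protocol`.
#' @export
default_protocol <- function(...) {
  acquisition_protocol(...)
}

#' Logarithmically spaced inversion times
#'
#' @param n number of inversion times (>= 2).
#' @param tmin,tmax first and last value in seconds, `0 < tmin < tmax`.
#' @return Numeric vector of length `n` with constant consecutive ratio,
#'   beginning exactly at `tmin` and ending exactly at `tmax`.
#' @export
log_spaced_inversion_times <- function(n, tmin, tmax) {
  if (n < 2) stop_arg("`n` must be >= 2")
  if (!(tmin > 0) || !(tmax > tmin)) stop_arg("need 0 < tmin < tmax")
  ti <- log_seq(tmin, tmax, n)
  ti[1] <- tmin
  ti[n] <- tmax
  ti
}

#' Inversion times of a protocol
#' @param protocol an `acquisition_protocol`.
#' @return TI vector in seconds.
#' @export
protocol_ti <- function(protocol) {
  log_spaced_inversion_times(protocol$n_inversions, protocol$ti_min, protocol$ti_max)
}

#' Echo times of a protocol
#' @param protocol an `acquisition_protocol`.
#' @return Echo acquisition times `TE, 2 TE, ..., n_echoes * TE` in seconds.
#' @export
protocol_echo_times <- function(protocol) {
  protocol$echo_spacing_te * seq_len(protocol$n_echoes)
}

#' IR-CPMG signal amplitude for a single relaxation component
#'
#' Ideal-pulse kernel of the combined experiment: longitudinal recovery
#' after a perfect 180 degree inversion followed by transverse decay in
#' the echo train,
#' `A * (1 - 2 * exp(-TI / T1)) * exp(-t / T2)`.
#' The signal crosses zero at the inversion null `TI = T1 * ln 2`.
#'
#' @param ti inversion time in seconds (> 0); vectorized.
#' @param t echo time since excitation in seconds (>= 0); vectorized.
#' @param component a [relaxation_component()].
#' @return Signal amplitude(s) in the component's units.
#' @export
ir_cpmg_amplitude <- function(ti, t, component) {
  if (any(ti <= 0)) stop_arg("`ti` must be positive")
  if (any(t < 0)) stop_arg("`t` must be nonnegative")
  component$amplitude *
    (1 - 2 * exp(-ti / component$t1)) *
    exp(-t / component$t2)
}
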