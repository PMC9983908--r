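#' Time-domain IR-CPMG data for one sample
#'
#' Container for a simulated (or imported) measurement: the TI vector,
#' the echo time axis, and the amplitude matrix
#' `n_inversions x n_echoes` (after intra-echo collapse), optionally
#' alongside the raw `n_inversions x n_echoes x points_per_echo` tensor.
#'
#' @param ti_vector inversion times, strictly increasing.
#' @param echo_times echo acquisition times, strictly increasing with
#'   constant spacing.
#' @param amplitudes matrix `length(ti_vector) x length(echo_times)`.
#' @param raw optional raw tensor with per-point sampling.
#' @param metadata list with at least `sample_id`, `phenotype`, `seed`.
#' @return Object of class `time_domain_data`.
#' @export
time_domain_data <- function(ti_vector, echo_times, amplitudes,
                             raw = NULL, metadata = list()) {
  if (is.unsorted(ti_vector, strictly = TRUE)) {
    stop_arg("`ti_vector` must be strictly increasing")
  }
  if (is.unsorted(echo_times, strictly = TRUE)) {
    stop_arg("`echo_times` must be strictly increasing")
  }
  stopifnot(nrow(amplitudes) == length(ti_vector),
            ncol(amplitudes) == length(echo_times))
  structure(list(ti_vector = ti_vector, echo_times = echo_times,
                 amplitudes = amplitudes, raw = raw, metadata = metadata),
            class = "time_domain_data")
}

## Noise-free forward model: sum of per-component IR-CPMG kernels on the
## TI x echo-time lattice, with component positions already jittered.
.forward_signal <- function(components, ti, t) {
  sig <- matrix(0, length(ti), length(t))
  for (co in components) {
    sig <- sig + co$amplitude *
      outer(1 - 2 * exp(-ti / co$t1), exp(-t / co$t2))
  }
  sig
}

#' Simulate one IR-CPMG measurement
#'
#' Draws each component's (T1, T2) position once per sample from its
#' log-normal jitter distribution, evaluates the ideal-pulse forward
#' model on the protocol's TI x echo-time lattice, and adds i.i.d.
#' Gaussian acquisition noise.  With `collapse = TRUE` (default) the 40
#' intra-echo points are never materialized: the returned matrix carries
#' noise of standard deviation `noise_sigma / sqrt(points_per_echo)`,
#' exactly the distribution of the per-echo mean of the raw points.
#' `collapse = FALSE` returns the raw tensor as well (intended for small
#' protocols).
#'
#' @param phenotype a [relaxation_phenotype()].
#' @param protocol an [acquisition_protocol()].
#' @param seed integer seed; identical inputs give bit-identical output.
#' @param sample_id identifier stored in the metadata.
#' @param collapse return collapsed per-echo amplitudes only.
#' @return A [time_domain_data()].
#' @export
simulate_sample <- function(phenotype, protocol, seed = protocol$seed,
                            sample_id = phenotype$name, collapse = TRUE) {
  stopifnot(inherits(phenotype, "relaxation_phenotype"),
            inherits(protocol, "acquisition_protocol"))
  ti <- protocol_ti(protocol)
  t <- protocol_echo_times(protocol)
  out <- with_seed(seed, {
    comps <- lapply(phenotype$components, function(co) {
      j1 <- stats::rnorm(1, 0, 1)
      j2 <- stats::rnorm(1, 0, 1)
      co$t1 <- 10^(log10(co$t1) + co$jitter_log_t1 * j1)
      co$t2 <- 10^(log10(co$t2) + co$jitter_log_t2 * j2)
      co
    })
    sig <- .forward_signal(comps, ti, t)
    if (collapse) {
      sd_eff <- protocol$noise_sigma / sqrt(protocol$points_per_echo)
      amp <- sig
      if (sd_eff > 0) amp <- amp + matrix(stats::rnorm(length(sig), 0, sd_eff),
                                          nrow(sig), ncol(sig))
      list(amplitudes = amp, raw = NULL, components = comps)
    } else {
      ppe <- protocol$points_per_echo
      raw <- array(rep(sig, ppe), dim = c(nrow(sig), ncol(sig), ppe))
      if (protocol$noise_sigma > 0) {
        raw <- raw + array(stats::rnorm(length(raw), 0, protocol$noise_sigma),
                           dim = dim(raw))
      }
      list(amplitudes = apply(raw, c(1, 2), mean), raw = raw, components = comps)
    }
  })
  time_domain_data(
    ti_vector = ti, echo_times = t, amplitudes = out$amplitudes, raw = out$raw,
    metadata = list(sample_id = sample_id, phenotype = phenotype$name,
                    seed = as.integer(seed),
                    jittered_components = out$components,
                    points_per_echo = protocol$points_per_echo,
                    noise_sigma = protocol$noise_sigma)
  )
}

#' Simulate a cohort of measurements from a manifest
#'
#' Emits `sum(n_replicates)` samples; every replicate's seed is derived
#' deterministically from the manifest seed, its group prefix and its
#' replicate index, so cohorts are reproducible and individual samples
#' can be regenerated in isolation.
#'
#' @param manifest a [cohort_manifest()].
#' @param phenotypes named phenotype library; defaults to
#'   [phenotype_library()].
#' @param protocol an [acquisition_protocol()].
#' @param collapse passed to [simulate_sample()].
#' @return Named list of [time_domain_data()], one per sample; each
#'   element's metadata carries the manifest's `class_label`.
#' @export
simulate_cohort <- function(manifest, phenotypes = phenotype_library(),
                            protocol = default_protocol(), collapse = TRUE) {
  missing <- setdiff(manifest$phenotype, names(phenotypes))
  if (length(missing)) {
    stop_arg("unknown phenotype(s) in manifest: ", paste(missing, collapse = ", "))
  }
  root <- attr(manifest, "seed")
  if (is.null(root)) root <- 1L
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    ph <- phenotypes[[manifest$phenotype[i]]]
    for (r in seq_len(manifest$n_replicates[i])) {
      sid <- sprintf("%s_%03d", manifest$sample_prefix[i], r)
      td <- simulate_sample(
        ph, protocol,
        seed = derive_seed(root, "simulate", manifest$sample_prefix[i], r),
        sample_id = sid, collapse = collapse
      )
      td$metadata$class_label <- manifest$class_label[i]
      out[[sid]] <- td
    }
  }
  out
}
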