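#' A single T1/T2 relaxation component
#'
#' One exponential component of a sample's relaxation signature: a
#' longitudinal time constant `t1`, a transverse time constant `t2`, an
#' equilibrium amplitude, and per-replicate positional jitter expressed
#' as standard deviations in log10 seconds.  A cell sample is modelled as
#' a mixture of such components (cell peak, media peak, and for
#' adipogenically differentiated MSCs an additional lipid peak).
#'
#' @param t1,t2 relaxation times in seconds (> 0).
#' @param amplitude equilibrium signal amplitude (>= 0).
#' @param jitter_log_t1,jitter_log_t2 replicate-to-replicate positional
#'   scatter, std dev in log10 seconds (>= 0).
#' @return An object of class `relaxation_component`.
#' @export
relaxation_component <- function(t1, t2, amplitude = 1,
                                 jitter_log_t1 = 0, jitter_log_t2 = 0) {
  if (!(t1 > 0) || !(t2 > 0)) stop_arg("`t1` and `t2` must be positive")
  if (amplitude < 0) stop_arg("`amplitude` must be >= 0")
  if (jitter_log_t1 < 0 || jitter_log_t2 < 0) stop_arg("jitters must be >= 0")
  structure(
    list(t1 = t1, t2 = t2, amplitude = amplitude,
         jitter_log_t1 = jitter_log_t1, jitter_log_t2 = jitter_log_t2),
    class = "relaxation_component"
  )
}

#' A relaxation phenotype: a named mixture of components
#'
#' @param name phenotype label, e.g. `"CHO"` or `"MSC_diff"`.
#' @param components list of [relaxation_component()] objects (>= 1).
#' @return Object of class `relaxation_phenotype`.
#' @export
relaxation_phenotype <- function(name, components) {
  if (length(components) < 1) stop_arg("phenotype needs >= 1 component")
  stopifnot(all(vapply(components, inherits, TRUE, "relaxation_component")))
  structure(list(name = name, components = components),
            class = "relaxation_phenotype")
}

## Default component geometry. The study never tabulates per-line (T1, T2)
## values, so these are package defaults chosen to reproduce the
## qualitative layout of the published spectra: cell peaks with T1 in
## 0.3-1.5 s and T2 in 0.02-0.3 s spread across lines, a common media
## peak near T1 = 2.5 s with long T2, and a lipid peak at shorter T1 /
## longer T2 than the aqueous cell peak for differentiated MSCs.
.cell_peak_positions <- list(
  A549    = c(0.55, 0.060),
  C2C12   = c(0.70, 0.045),
  CHO     = c(0.45, 0.035),
  HEK293T = c(0.80, 0.080),
  HeLa    = c(0.60, 0.110),
  K562    = c(1.00, 0.070),
  L929    = c(0.90, 0.150),
  MDA231  = c(0.50, 0.090),
  THP1    = c(1.20, 0.100),
  Vero    = c(0.75, 0.028)
)

.media_component <- function() {
  relaxation_component(t1 = 2.5, t2 = 2.0, amplitude = 1.2,
                       jitter_log_t1 = 0.01, jitter_log_t2 = 0.01)
}

.cell_component <- function(t1, t2, amplitude = 1,
                            jitter = 0.03) {
  relaxation_component(t1 = t1, t2 = t2, amplitude = amplitude,
                       jitter_log_t1 = jitter, jitter_log_t2 = jitter)
}

#' Default phenotype library
#'
#' A named list of [relaxation_phenotype()] objects emulating the study
#' system: ten immortalized cell lines, undifferentiated and
#' adipogenically differentiated mesenchymal stromal cells (the latter
#' carrying an extra lipid peak), a media-only sample, and the agarose
#' contrast-agent cell phantom (ADCP).  The (T1, T2) positions are
#' package defaults, not measured values.
#'
#' @param cell_jitter per-replicate positional scatter of cell peaks,
#'   std dev in log10 seconds.
#' @return Named list of phenotypes.
#' @export
phenotype_library <- function(cell_jitter = 0.03) {
  lines <- lapply(names(.cell_peak_positions), function(nm) {
    p <- .cell_peak_positions[[nm]]
    relaxation_phenotype(nm, list(
      .cell_component(p[1], p[2], jitter = cell_jitter),
      .media_component()
    ))
  })
  names(lines) <- names(.cell_peak_positions)
  lines$MSC_undiff <- relaxation_phenotype("MSC_undiff", list(
    .cell_component(0.65, 0.075, jitter = cell_jitter),
    .media_component()
  ))
  ## differentiation adds intracellular lipid: shorter T1, longer T2 than
  ## the aqueous cell peak
  lines$MSC_diff <- relaxation_phenotype("MSC_diff", list(
    .cell_component(0.68, 0.080, jitter = cell_jitter),
    .cell_component(0.15, 0.180, amplitude = 0.55, jitter = cell_jitter),
    .media_component()
  ))
  lines$media_only <- relaxation_phenotype("media_only", list(.media_component()))
  lines$ADCP <- make_adcp_phantom()
  lines
}

#' Agarose contrast-agent cell phantom (ADCP)
#'
#' A single-component phenotype mimicking the T1/T2 signature of a
#' CHO-like cell peak, as produced by a Dotagraf-doped agarose gel.
#' Used for scanner stability checks: its peak position is expected to be
#' independent of sample volume and stable over time.
#'
#' @param t1,t2 phantom relaxation times in seconds.
#' @param amplitude equilibrium amplitude.
#' @param jitter replicate scatter, std dev in log10 seconds (small for a
#'   homogeneous gel).
#' @return A single-component `relaxation_phenotype` named `"ADCP"`.
#' @export
make_adcp_phantom <- function(t1 = 0.45, t2 = 0.035, amplitude = 1,
                              jitter = 0.01) {
  relaxation_phenotype("ADCP", list(
    relaxation_component(t1 = t1, t2 = t2, amplitude = amplitude,
                         jitter_log_t1 = jitter, jitter_log_t2 = jitter)
  ))
}

#' Cohort manifest
#'
#' One row per biological group to simulate: a sample-id prefix, the
#' phenotype to draw from, the class label used downstream by the
#' classifiers, and the number of independent replicates.
#'
#' @param phenotype character vector of phenotype names.
#' @param n_replicates integer vector of replicate counts (>= 1).
#' @param class_label class labels; defaults to the phenotype names.
#' @param sample_prefix prefixes for generated sample ids.
#' @param seed root seed for the cohort.
#' @return A `data.frame` of class `cohort_manifest`.
#' @export
cohort_manifest <- function(phenotype, n_replicates,
                            class_label = phenotype,
                            sample_prefix = phenotype,
                            seed = 1L) {
  if (any(n_replicates < 1)) stop_arg("`n_replicates` must be >= 1")
  if (anyDuplicated(sample_prefix)) stop_arg("sample prefixes must be unique")
  m <- data.frame(
    sample_prefix = sample_prefix,
    phenotype = phenotype,
    class_label = class_label,
    n_replicates = as.integer(n_replicates),
    stringsAsFactors = FALSE
  )
  attr(m, "seed") <- as.integer(seed)
  class(m) <- c("cohort_manifest", "data.frame")
  m
}

## Per-line replicate counts as reported by the source study.
.per_line_counts <- c(A549 = 17L, C2C12 = 30L, CHO = 61L, HEK293T = 21L,
                 HeLa = 24L, K562 = 57L, L929 = 30L, MDA231 = 57L,
                 THP1 = 26L, Vero = 16L)

#' Manifest emulating the published dataset composition
#'
#' Two variants are shipped because the source study reports two
#' inconsistent totals.  Variant `"per_line"` uses the reported
#' per-line replicate counts (A549 17, C2C12 30, CHO 61, HEK293T 21,
#' HeLa 24, K562 57, L929 30, MDA231 57, THP1 26, Vero 16; sum 339),
#' plus 8 undifferentiated and 7 differentiated MSC samples, for 354
#' samples in total.  Variant `"full"` tops the five largest lines up
#' by 3 replicates each so that the cell lines sum to the study's
#' stated 354 replicates, giving its 369-sample overall composition.
#' The 15 added replicates are a labelled reconstruction: their
#' per-line distribution is not reported anywhere.
#'
#' @param variant `"full"` (default, 369 samples) or `"per_line"` (354).
#' @param seed root seed.
#' @return A [cohort_manifest()].
#' @export
study_manifest <- function(variant = c("full", "per_line"), seed = 1L) {
  variant <- match.arg(variant)
  counts <- .per_line_counts
  if (variant == "full") {
    topup <- c("CHO", "K562", "MDA231", "C2C12", "HeLa")
    counts[topup] <- counts[topup] + 3L
  }
  cohort_manifest(
    phenotype = c(names(counts), "MSC_undiff", "MSC_diff"),
    n_replicates = c(unname(counts), 8L, 7L),
    seed = seed
  )
}

#' Write / read a phenotype library as CSV
#'
#' Long format, one row per component:
#' `phenotype, t1, t2, amplitude, jitter_log_t1, jitter_log_t2`.
#'
#' @param library named list of phenotypes.
#' @param path file path.
#' @return `read_phenotypes_csv` returns the named list of phenotypes.
#' @export
write_phenotypes_csv <- function(library, path) {
  rows <- do.call(rbind, lapply(library, function(ph) {
    do.call(rbind, lapply(ph$components, function(co) {
      data.frame(phenotype = ph$name, t1 = co$t1, t2 = co$t2,
                 amplitude = co$amplitude,
                 jitter_log_t1 = co$jitter_log_t1,
                 jitter_log_t2 = co$jitter_log_t2)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("phenotype", "t1", "t2", "amplitude", "jitter_log_t1", "jitter_log_t2")
  if (!all(need %in% names(rows))) {
    stop_arg("phenotype CSV must have columns: ", paste(need, collapse = ", "))
  }
  lapply(split(rows, rows$phenotype)[unique(rows$phenotype)], function(d) {
    comps <- lapply(seq_len(nrow(d)), function(i) {
      relaxation_component(d$t1[i], d$t2[i], d$amplitude[i],
                           d$jitter_log_t1[i], d$jitter_log_t2[i])
    })
    relaxation_phenotype(d$phenotype[1], comps)
  })
}
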