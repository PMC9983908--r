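#!/usr/bin/env Rscript
# Reconstruct T1/T2 spectra for the analysis cohort.
#
# Chain per sample: collapse intra-echo points, re-grid the 5000-echo
# train onto 256 logarithmic bins, max-normalize, PCA noise reduction
# (rank 8), T1 polarity orientation, then the Tikhonov-regularized
# nonnegative 2D inverse Laplace transform with SVD-compressed kernels.
# A 100 x 100 grid is used here (300 x 300 reproduces the full-
# resolution setting at ~9x the cost).  MSC samples get a deeper
# iteration budget because the lipid and water cell peaks lie close
# together and only separate once the solver is well converged.

library(relaxcell)

seed <- 1L
out_dir <- "results"
man <- utils::read.csv(file.path(out_dir, "manifest_analysis.csv"))
attr(man, "seed") <- seed
class(man) <- c("cohort_manifest", "data.frame")

is_msc <- grepl("MSC", man$phenotype)
spec_cell <- cohort_spectra(man[!is_msc, ], grid_n = 100L,
                            alpha = 1e-3, max_iter = 3000L)
spec_msc <- cohort_spectra(man[is_msc, ], grid_n = 100L,
                           alpha = 1e-3, max_iter = 8000L)
spectra <- c(spec_cell, spec_msc)
message(sprintf("reconstructed %d spectra", length(spectra)))

dir.create(file.path(out_dir, "spectra"), showWarnings = FALSE)
for (s in spectra) {
  write_spectrum_csv(s, file.path(out_dir, "spectra",
                                  paste0(s$metadata$sample_id, ".csv")))
}

# peak census: cell lines should show cell + media, differentiated MSCs
# mostly a third (lipid) peak
census <- do.call(rbind, lapply(spectra, function(s) {
  pk <- tag_peaks(detect_peaks(s))
  data.frame(sample_id = s$metadata$sample_id,
             class_label = s$metadata$class_label,
             n_peaks = length(pk),
             tags = paste(vapply(pk, `[[`, "", "tag"), collapse = "+"))
}))
utils::write.csv(census, file.path(out_dir, "peak_census.csv"),
                 row.names = FALSE)
tab <- table(census$class_label, census$n_peaks)
print(tab)
message("differentiated MSC replicates with 3 peaks: ",
        sum(census$n_peaks[census$class_label == "MSC_diff"] == 3),
        " of ", sum(census$class_label == "MSC_diff"))

write_provenance(file.path(out_dir, "provenance_reconstruct.json"),
                 default_run_config(seed), seed,
                 extra = list(stage = "reconstruct", n_spectra = length(spectra)))
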