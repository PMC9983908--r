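#!/usr/bin/env Rscript
# Simulate the synthetic study cohort.
#
# Emulates the measured dataset: ten immortalized cell lines plus
# undifferentiated / adipogenically differentiated MSCs, acquired with a
# 32-step inversion-recovery CPMG protocol (TI 5 ms - 15 s, 5000 echoes
# at TE = 3 ms).  The full composition manifest (369 samples, text
# variant) is written for reference; the analyses that follow use a
# reduced cohort (8 replicates per line, all 15 MSC samples) so that the
# whole workflow runs in minutes on one CPU.

library(relaxcell)

seed <- 1L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- default_run_config(seed)
write_run_config(cfg, file.path(out_dir, "run_config.yaml"))

# full published composition, both variants (the two reported totals
# disagree; see ?study_manifest)
for (v in c("full", "per_line")) {
  m <- study_manifest(v, seed = seed)
  utils::write.csv(m, file.path(out_dir, sprintf("manifest_%s.csv", v)),
                   row.names = FALSE)
  message(sprintf("manifest '%s': %d samples", v, sum(m$n_replicates)))
}

write_phenotypes_csv(phenotype_library(),
                     file.path(out_dir, "phenotype_library.csv"))

# reduced analysis cohort
lines <- c("A549", "C2C12", "CHO", "HEK293T", "HeLa",
           "K562", "L929", "MDA231", "THP1", "Vero")
man <- cohort_manifest(c(lines, "MSC_undiff", "MSC_diff"),
                       c(rep(8L, 10), 8L, 7L), seed = seed)
utils::write.csv(man, file.path(out_dir, "manifest_analysis.csv"),
                 row.names = FALSE)

cohort <- simulate_cohort(man)
message(sprintf("simulated %d time-domain samples (32 x %d points each)",
                length(cohort), ncol(cohort[[1]]$amplitudes)))

# one exemplar time-domain export per phenotype family
dir.create(file.path(out_dir, "timedomain"), showWarnings = FALSE)
for (sid in c("CHO_001", "MSC_diff_001")) {
  write_timedomain_csv(cohort[[sid]],
                       file.path(out_dir, "timedomain", paste0(sid, ".csv")))
}

write_provenance(file.path(out_dir, "provenance_simulate.json"), cfg, seed,
                 extra = list(stage = "simulate", n_samples = length(cohort)))
message("done: manifests, phenotype library and exemplar exports in results/")
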