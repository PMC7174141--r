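#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study with known ground truth.
#
# Emulates the structure of a household fecal-contamination survey:
# plasmid standard dilution series spread over instrument runs and
# extraction batches, a host-labeled assay validation panel, and an
# environmental sampling campaign (compounds x households x five sample
# types) with qPCR reactions, culture plates, covariates and meteorology.

suppressPackageStartupMessages(library(mstquant))

seed <- 1L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

truth <- sim_truth()  # study conditions; see ?sim_truth for the defaults

standards <- simulate_standards(truth, n_runs = 4, n_batches = 3,
                                levels = 5:1, reps = 3, seed = seed)
panel <- simulate_validation_panel(n_target = 14, n_nontarget = 27,
                                   sensitivity = 0.8, cross_rate = 0.05,
                                   seed = seed)
env <- simulate_environment(truth, n_compounds = 20,
                            households_per_compound = 2, seed = seed)

write.csv(standards, file.path(out_dir, "standards.csv"),
          row.names = FALSE)
write.csv(panel, file.path(out_dir, "validation_panel.csv"),
          row.names = FALSE)
for (nm in c("samples", "reactions", "plates", "covariates",
             "meteorology")) {
  write.csv(env[[nm]], file.path(out_dir, paste0(nm, ".csv")),
            row.names = FALSE)
}
# later stages regenerate `env` deterministically from the same seed, so
# the CSVs above are the complete interchange record

cat(sprintf("standards: %d reactions over %d runs x %d batches\n",
            nrow(standards), 4, 3))
cat(sprintf("validation panel: %d reactions from %d samples\n",
            nrow(panel), length(unique(panel$sample_id))))
cat(sprintf("environment: %d samples in %d compounds; %d reactions, %d plates\n",
            nrow(env$samples), 20, nrow(env$reactions), nrow(env$plates)))
cat(sprintf("nondetect qPCR fraction: %.2f\n",
            mean(is.na(env$reactions$cq))))
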