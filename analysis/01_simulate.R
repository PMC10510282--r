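#!/usr/bin/env Rscript
# Step 1: simulate the TRAP-Seq experiment.
#
# Generates the default 4-genotype x 3-treatment factorial (5 replicates per
# group) with planted gene classes and writes the count table, sample sheet
# and ground truth under results/data/. Downstream steps read these files,
# mimicking an analysis that starts from a featureCounts table.

library(trapdiff)

out_dir <- file.path("results", "data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260918)
sim <- simulate_experiment(cfg)

write_counts(sim$counts, file.path(out_dir, "counts.tsv"),
             file.path(out_dir, "sample_sheet.tsv"))
write_truth(sim$truth, file.path(out_dir, "truth.tsv"))

message(sprintf("simulated %d genes x %d samples", nrow(sim$counts$counts),
                ncol(sim$counts$counts)))
print(table(planted_class = sim$truth$class))
message("library-size factors span ",
        paste(round(range(sim$size_factors), 2), collapse = " - "))
message("wrote counts, sample sheet and truth under ", out_dir)
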