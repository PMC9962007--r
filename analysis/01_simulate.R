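#!/usr/bin/env Rscript
# Stage 1: generate the synthetic standards library and its simulated
# measurements (the stand-in for an in-house standards campaign), and write
# the tables every later stage reads.

library(ccsrt)

seed <- 1L
dir.create("results", showWarnings = FALSE)

lib <- generate_library(200, seed = seed)
meas <- simulate_measurements(lib, seed = seed + 1L)

cat(sprintf("library: %d compounds (classes: %s)\n", nrow(lib$records),
            paste(table(lib$records$class), collapse = "/")))
cat(sprintf("measured: %d Rt values, %d CCS adduct values (%d compounds)\n",
            nrow(meas$standards), nrow(meas$ccs_entries),
            length(unique(meas$ccs_entries$id))))
cat(sprintf("descriptor-incomplete compounds: %d\n",
            sum(meas$standards$descriptor_incomplete)))

write.csv(meas$standards, "results/standards.csv", row.names = FALSE)
write.csv(meas$ccs_entries, "results/ccs_entries.csv", row.names = FALSE)
write.csv(lib$records, "results/library_truth.csv", row.names = FALSE)
saveRDS(lib, "results/library.rds")   # descriptors reused downstream
cat("wrote results/standards.csv, results/ccs_entries.csv\n")
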