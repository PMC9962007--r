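#!/usr/bin/env Rscript
# Stage 5: assemble the predicted (metabolite, adduct) annotation database
# over the full candidate pool and merge the measured standards entries,
# which take precedence over predictions.

library(ccsrt)

lib <- readRDS("results/library.rds")
rt_model <- readRDS("results/rt_model.rds")
ccs_model <- readRDS("results/ccs_model.rds")
ccs <- read.csv("results/ccs_entries.csv", stringsAsFactors = FALSE)
std <- read.csv("results/standards.csv", stringsAsFactors = FALSE)

pool <- metabolite_pool()
extra <- pool[!pool$smiles %in% lib$records$smiles, ]
candidates <- rbind(
  lib$records[, c("id", "name", "formula", "smiles")],
  data.frame(id = sprintf("POOL%04d", seq_len(nrow(extra))),
             name = extra$name, formula = NA_character_,
             smiles = extra$smiles, stringsAsFactors = FALSE))

built <- build_database(candidates, ccs_model, rt_model)
cat(sprintf("predicted: %d rows over %d candidates (%d rejects)\n",
            nrow(built$entries), nrow(candidates), nrow(built$rejects)))

measured <- data.frame(metabolite_id = ccs$id, adduct = ccs$adduct,
                       mz = ccs$mz, ccs_A2 = ccs$ccs_A2,
                       rt_min = std$rt_min[match(ccs$id, std$id)],
                       polarity = ccs$polarity, stringsAsFactors = FALSE)
db <- merge_measured(built$entries, measured)
cat(sprintf("after merging standards: %d rows (%d measured)\n",
            nrow(db), sum(db$source == "measured")))

write_database(db, "results/database.csv")
cat("wrote results/database.csv\n")
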