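#!/usr/bin/env Rscript
# Stage 3: train the cluster-based CCS model on the measured (compound,
# adduct) entries and evaluate on a held-out split.

library(ccsrt)

seed <- 1L
lib <- readRDS("results/library.rds")
ccs <- read.csv("results/ccs_entries.csv", stringsAsFactors = FALSE)

desc <- lib$descriptors[match(ccs$id, lib$records$id), ]
set.seed(seed + 5L)
train <- sort(sample.int(nrow(ccs), round(0.8 * nrow(ccs))))
test <- setdiff(seq_len(nrow(ccs)), train)

model <- fit_ccs_model(desc[train, ], ccs$mz[train], ccs$adduct[train],
                       ccs$ccs_A2[train], n_clusters = "auto",
                       seed = seed + 6L)
print(model)

pred <- predict_ccs_features(model, desc[test, ], ccs$mz[test],
                             ccs$adduct[test])
ok <- pred$ok
cat(sprintf("held-out (%d entries): MAE %.2f A^2\n", sum(ok),
            mean(abs(pred$ccs_pred[ok] - ccs$ccs_A2[test][ok]))))

saveRDS(model, "results/ccs_model.rds")
write.csv(data.frame(id = ccs$id[test][ok], adduct = ccs$adduct[test][ok],
                     measured = ccs$ccs_A2[test][ok],
                     predicted = pred$ccs_pred[ok]),
          "results/ccs_validation.csv", row.names = FALSE)
cat("wrote results/ccs_model.rds, results/ccs_validation.csv\n")
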