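#!/usr/bin/env Rscript
# Stage 2: train the QSRR retention-time model on the standards and
# estimate out-of-sample accuracy by 10-fold cross-validation.

library(ccsrt)

seed <- 1L
lib <- readRDS("results/library.rds")
std <- read.csv("results/standards.csv", stringsAsFactors = FALSE)

desc <- lib$descriptors
desc[std$descriptor_incomplete, ] <- NA    # exclusion path, as in real runs
ts <- build_rt_training_set(std, descriptors = desc)
cat(sprintf("%d compounds retained, %d excluded for incomplete descriptors\n",
            length(ts$rt), length(ts$excluded)))

set.seed(seed + 2L)
train <- sort(sample.int(length(ts$rt), round(0.8 * length(ts$rt))))
model <- fit_rt_model(ts$descriptors[train, ], ts$rt[train], seed = seed + 3L)
cv <- cross_validate_rt(ts$descriptors[train, ], ts$rt[train], folds = 10,
                        seed = seed + 4L)
model$cv_metrics <- cv[c("mean_r2", "mean_mae", "sd_mae")]
print(model)

holdout <- setdiff(seq_along(ts$rt), train)
pred <- predict_rt(model, descriptors = ts$descriptors[holdout, ])
cat(sprintf("held-out (%d compounds): MAE %.3f min\n", length(holdout),
            mean(abs(pred$rt_pred - ts$rt[holdout]))))

saveRDS(model, "results/rt_model.rds")
write.csv(cv$per_fold, "results/rt_cv_folds.csv", row.names = FALSE)
cat("wrote results/rt_model.rds, results/rt_cv_folds.csv\n")
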