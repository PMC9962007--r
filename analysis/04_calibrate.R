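#!/usr/bin/env Rscript
# Stage 4: compare predicted against measured values and derive the
# MAE + 2 SD tolerance windows used by the annotation filter.

library(ccsrt)

val <- read.csv("results/ccs_validation.csv", stringsAsFactors = FALSE)
ccs_cal <- calibrate_property(val$predicted, val$measured, "ccs")
print(ccs_cal)

rt_model <- readRDS("results/rt_model.rds")
rt_tol <- rt_tolerance_from_cv(rt_model$cv_metrics)
cat(sprintf("Rt tolerance (CV mean MAE %.3f + 2 x SD %.3f) = %.3f min\n",
            rt_model$cv_metrics$mean_mae, rt_model$cv_metrics$sd_mae, rt_tol))

jsonlite::write_json(list(ccs = unclass(ccs_cal),
                          rt_tolerance_min = rt_tol),
                     "results/calibration.json", auto_unbox = TRUE,
                     digits = NA)
cat("wrote results/calibration.json\n")
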