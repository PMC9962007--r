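# Shared fixtures, computed once per test run and cached. Everything is
# generated in code under fixed seeds; no data files are read.

.fx <- new.env(parent = emptyenv())

fx_library <- function(n = 200, seed = 1) {
  key <- sprintf("lib_%d_%d", n, seed)
  if (is.null(.fx[[key]])) .fx[[key]] <- generate_library(n, seed = seed)
  .fx[[key]]
}

fx_measurements <- function(n = 200, seed = 1) {
  key <- sprintf("meas_%d_%d", n, seed)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- simulate_measurements(fx_library(n, seed), seed = seed + 1)
  }
  .fx[[key]]
}

# the full pipeline at the generator's default study conditions
fx_pipeline <- function() {
  if (is.null(.fx$pipe)) {
    .fx$pipe <- run_pipeline(pipeline_config(seed = 1, n_library = 200))
  }
  .fx$pipe
}

# a small fabricated database table (no models involved)
fx_fake_db <- function(n = 80, seed = 42) {
  set.seed(seed)
  data.frame(
    metabolite_id = sprintf("M%03d", seq_len(n)),
    name = sprintf("compound %d", seq_len(n)),
    formula = "C6H12O6",
    adduct = sample(c("[M+H]+", "[M-H]-"), n, replace = TRUE),
    polarity = NA_character_,
    mz = round(stats::runif(n, 100, 900), 4),
    ccs_A2 = round(stats::runif(n, 130, 300), 4),
    rt_min = round(stats::runif(n, 1, 16), 4),
    ccs_flag = FALSE, rt_flag = FALSE,
    source = "predicted",
    stringsAsFactors = FALSE
  ) -> db
  db$polarity <- ifelse(db$adduct == "[M+H]+", "positive", "negative")
  db
}

# exhaustive double-loop matching oracle, deliberately independent of the
# package's indexed matcher
oracle_match <- function(features, db, mz_tol, ccs_tol = NULL, rt_tol = NULL) {
  hits <- list()
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    for (j in seq_len(nrow(db))) {
      r <- db[j, ]
      if (r$polarity != f$polarity) next
      if (abs(f$mz - r$mz) > mz_tol) next
      if (!is.null(ccs_tol) && abs(f$ccs_A2 - r$ccs_A2) > ccs_tol) next
      if (!is.null(rt_tol) && abs(f$rt_min - r$rt_min) > rt_tol) next
      hits[[length(hits) + 1L]] <- data.frame(
        feature_id = f$feature_id, metabolite_id = r$metabolite_id,
        adduct = r$adduct, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(feature_id = character(), metabolite_id = character(),
                      adduct = character()))
  }
  do.call(rbind, hits)
}

hit_key <- function(df) sort(paste(df$feature_id, df$metabolite_id, df$adduct))
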