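# Feature-database matching under both identification strategies, hit
# statistics, and candidate ranking.

simple_db <- function() {
  data.frame(
    metabolite_id = c("M1", "M2", "M3"),
    name = c("a", "b", "c"), formula = NA_character_,
    adduct = c("[M+H]+", "[M+H]+", "[M-H]-"),
    polarity = c("positive", "positive", "negative"),
    mz = c(150.0000, 150.0040, 150.0000),
    ccs_A2 = c(140, 160, 140), rt_min = c(5, 5, 5),
    ccs_flag = FALSE, rt_flag = FALSE, source = "predicted",
    stringsAsFactors = FALSE)
}

test_that("exact match hits with zero errors; boundaries are inclusive", {
  db <- simple_db()
  f <- data.frame(feature_id = "F1", mz = 150.0000, polarity = "positive",
                  rt_min = 5, ccs_A2 = 140, stringsAsFactors = FALSE)
  s2 <- match_strategy(use_ccs = TRUE, use_rt = TRUE)
  h <- match_feature(f, db, s2)
  expect_equal(h$metabolite_id, "M1")
  expect_equal(h$dmz, 0); expect_equal(h$dccs, 0); expect_equal(h$drt, 0)
  # exactly at the m/z boundary: still a hit
  f_edge <- transform(f, mz = 150.0050)
  h_edge <- match_feature(f_edge, db, match_strategy(mz_tol = 0.005))
  expect_true("M1" %in% h_edge$metabolite_id)
  # 6 mDa off with a 5 mDa window: no hit
  f_off <- transform(f, mz = 150.0060)
  h_off <- match_feature(f_off, db, match_strategy(mz_tol = 0.005))
  expect_false("M1" %in% h_off$metabolite_id)
  # polarity is respected
  f_neg <- transform(f, polarity = "negative")
  h_neg <- match_feature(f_neg, db, match_strategy(mz_tol = 0.005))
  expect_equal(h_neg$metabolite_id, "M3")
})

test_that("CCS window excludes an m/z match beyond the tolerance", {
  db <- simple_db()
  db$ccs_A2[1] <- 140 + 17      # 17 A^2 away from the feature
  f <- data.frame(feature_id = "F1", mz = 150.0000, polarity = "positive",
                  rt_min = 5, ccs_A2 = 140, stringsAsFactors = FALSE)
  s1 <- match_strategy(mz_tol = 0.005)
  s2 <- match_strategy(mz_tol = 0.005, use_ccs = TRUE, ccs_tol = 16,
                       use_rt = TRUE, rt_tol = 1.1)
  expect_true("M1" %in% match_feature(f, db, s1)$metabolite_id)
  expect_false("M1" %in% match_feature(f, db, s2)$metabolite_id)
})

test_that("missing-dimension policy passes or fails as configured", {
  db <- simple_db()
  f <- data.frame(feature_id = "F1", mz = 150.0000, polarity = "positive",
                  rt_min = 5, ccs_A2 = NA_real_, stringsAsFactors = FALSE)
  s_pass <- match_strategy(use_ccs = TRUE, use_rt = TRUE)
  s_fail <- match_strategy(use_ccs = TRUE, use_rt = TRUE,
                           missing_dim = "fail")
  expect_warning(h1 <- match_feature(f, db, s_pass), "enabled dimension")
  expect_true("M1" %in% h1$metabolite_id)
  expect_warning(h2 <- match_feature(f, db, s_fail), "enabled dimension")
  expect_equal(nrow(h2), 0)
})

test_that("indexed matcher equals the exhaustive double-loop oracle", {
  set.seed(61)
  db <- fx_fake_db(500, seed = 71)
  # features: half jittered copies of db rows, half random
  rows <- sample(500, 25)
  features <- rbind(
    data.frame(feature_id = sprintf("T%02d", 1:25),
               mz = db$mz[rows] + runif(25, -0.006, 0.006),
               polarity = db$polarity[rows],
               rt_min = db$rt_min[rows] + runif(25, -1.5, 1.5),
               ccs_A2 = db$ccs_A2[rows] + runif(25, -20, 20),
               intensity = 1, stringsAsFactors = FALSE),
    data.frame(feature_id = sprintf("R%02d", 1:25),
               mz = runif(25, 100, 900),
               polarity = sample(c("positive", "negative"), 25, TRUE),
               rt_min = runif(25, 1, 16), ccs_A2 = runif(25, 130, 300),
               intensity = 1, stringsAsFactors = FALSE))
  s1 <- match_strategy(mz_tol = 0.005)
  s2 <- match_strategy(mz_tol = 0.005, use_ccs = TRUE, ccs_tol = 16,
                       use_rt = TRUE, rt_tol = 1.1)
  r1 <- annotate_table(features, db, s1)
  r2 <- annotate_table(features, db, s2)
  expect_identical(hit_key(r1$hits),
                   hit_key(oracle_match(features, db, 0.005)))
  expect_identical(hit_key(r2$hits),
                   hit_key(oracle_match(features, db, 0.005, 16, 1.1)))
  # strategy 2 hits are a subset of strategy 1 hits, per feature
  expect_true(all(hit_key(r2$hits) %in% hit_key(r1$hits)))
  # distribution bins conserve the feature count
  expect_equal(sum(r1$bins), r1$n_features)
  expect_equal(sum(r2$bins), r2$n_features)
  expect_equal(r1$total_hits, sum(r1$per_feature$n_hits))
})

test_that("matching is invariant to row order of db and features", {
  db <- fx_fake_db(200, seed = 81)
  features <- data.frame(
    feature_id = sprintf("F%02d", 1:20),
    mz = db$mz[1:20] + runif(20, -0.004, 0.004),
    polarity = db$polarity[1:20],
    rt_min = db$rt_min[1:20], ccs_A2 = db$ccs_A2[1:20],
    intensity = 1, stringsAsFactors = FALSE)
  s <- match_strategy(use_ccs = TRUE, use_rt = TRUE)
  r <- annotate_table(features, db, s)
  set.seed(3)
  r_shuf <- annotate_table(features[sample(20), ], db[sample(200), ], s)
  expect_identical(hit_key(r$hits), hit_key(r_shuf$hits))
  expect_equal(sort(r$per_feature$n_hits), sort(r_shuf$per_feature$n_hits))
})

test_that("empty inputs produce empty reports", {
  db <- simple_db()
  s <- match_strategy()
  no_features <- data.frame(feature_id = character(), mz = numeric(),
                            polarity = character(), stringsAsFactors = FALSE)
  r0 <- annotate_table(no_features, db, s)
  expect_equal(r0$n_features, 0)
  expect_equal(r0$total_hits, 0)
  r_empty_db <- annotate_table(
    data.frame(feature_id = "F1", mz = 150, polarity = "positive",
               stringsAsFactors = FALSE), db[0, ], s)
  expect_equal(r_empty_db$total_hits, 0)
  expect_equal(r_empty_db$bins[["0"]], 1)
})

test_that("hit statistics compute integer percentages and filtering rate", {
  db <- fx_fake_db(300, seed = 91)
  features <- data.frame(
    feature_id = sprintf("F%02d", 1:30),
    mz = db$mz[1:30] + runif(30, -0.004, 0.004),
    polarity = db$polarity[1:30],
    rt_min = db$rt_min[1:30] + runif(30, -0.5, 0.5),
    ccs_A2 = db$ccs_A2[1:30] + runif(30, -5, 5),
    intensity = 1, stringsAsFactors = FALSE)
  s1 <- match_strategy()
  s2 <- match_strategy(use_ccs = TRUE, use_rt = TRUE)
  r1 <- annotate_table(features, db, s1)
  r2 <- annotate_table(features, db, s2)
  st <- hit_statistics(r1, r2)
  expect_equal(st$pct_hits_filtered,
               100 * (r1$total_hits - r2$total_hits) / r1$total_hits)
  # identical reports: nothing filtered, no bin shifts
  same <- hit_statistics(r1, r1)
  expect_equal(same$pct_hits_filtered, 0)
  expect_equal(same$delta_single_hit_pct, 0)
  expect_equal(same$delta_gt10_pct, 0)
  # mismatched feature sets abort
  r_sub <- annotate_table(features[1:10, ], db, s1)
  expect_error(hit_statistics(r1, r_sub), "comparison error")
})

test_that("candidate ranking is dominance-ordered with deterministic ties", {
  hits <- data.frame(
    feature_id = "F1",
    metabolite_id = c("MB", "MA", "MC"),
    adduct = "[M+H]+",
    dmz = c(0.004, 0.001, 0.002),
    dccs = c(10, 2, 4), drt = c(0.9, 0.1, 0.3),
    score = c(0.8, 0.1, 0.3), stringsAsFactors = FALSE)
  r <- rank_candidates(hits)
  expect_equal(r$metabolite_id, c("MA", "MC", "MB"))
  expect_equal(r$rank, 1:3)
  # constructed tie on score: metabolite id decides
  tie <- data.frame(feature_id = "F1", metabolite_id = c("MZ", "MA"),
                    adduct = "[M+H]+", dmz = c(0.002, 0.002),
                    dccs = c(3, 3), drt = c(0.2, 0.2),
                    score = c(0.25, 0.25), stringsAsFactors = FALSE)
  rt <- rank_candidates(tie)
  expect_equal(rt$metabolite_id, c("MA", "MZ"))
  # single hit is rank 1
  expect_equal(rank_candidates(hits[1, ])$rank, 1)
})

test_that("per-metabolite collapse keeps the best adduct row", {
  hits <- data.frame(
    feature_id = c("F1", "F1", "F1"),
    metabolite_id = c("MA", "MA", "MB"),
    adduct = c("[M+H]+", "[M+Na]+", "[M+H]+"),
    dmz = c(0.001, 0.003, 0.002), dccs = c(1, 5, 2), drt = c(0.1, 0.4, 0.2),
    score = c(0.1, 0.5, 0.2), stringsAsFactors = FALSE)
  col <- collapse_hits_by_metabolite(hits)
  expect_equal(nrow(col), 2)
  expect_equal(col$adduct[col$metabolite_id == "MA"], "[M+H]+")
})
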