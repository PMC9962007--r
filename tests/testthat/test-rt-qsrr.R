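# Descriptor filtering and the QSRR retention-time model.

make_matrix <- function(n = 50, p = 30, seed = 3) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("d", seq_len(p))))
  m
}

test_that("descriptor filter drops missing, constant and duplicate columns", {
  m <- make_matrix(40, 6)
  m[, 2] <- 7                 # constant
  m[, 4] <- m[, 1]            # exact duplicate of an earlier column
  m[5, 6] <- NA               # one missing value
  keep <- filter_descriptors(m)
  expect_false(2 %in% keep)
  expect_false(6 %in% keep)
  expect_true(1 %in% keep)    # earlier-indexed member of the pair survives
  expect_false(4 %in% keep)
  expect_error(filter_descriptors(matrix(1, 5, 2)), "degenerate-input")
})

test_that("descriptor filter agrees with the exhaustive pairwise oracle", {
  m <- make_matrix(50, 30, seed = 11)
  # plant correlated pairs
  m[, 8] <- m[, 3] + rnorm(50, 0, 0.01)
  m[, 20] <- -m[, 12] + rnorm(50, 0, 0.01)
  thr <- 0.95
  keep <- filter_descriptors(m, cor_threshold = thr)
  # fixpoint property checked by brute force over all column pairs: a
  # column is retained iff no retained earlier column correlates above the
  # threshold with it
  cm <- abs(cor(m))
  for (j in seq_len(ncol(m))) {
    earlier <- keep[keep < j]
    conflicted <- length(earlier) > 0 && any(cm[earlier, j] > thr)
    if (j %in% keep) expect_false(conflicted)
    else expect_true(conflicted)
  }
})

test_that("noiseless linear retention surface is learned almost exactly", {
  m <- make_matrix(60, 10, seed = 5)
  rt <- 8 + 2 * m[, 1] - 1.5 * m[, 4] + 0.8 * m[, 7]
  fit <- fit_rt_model(m, rt, seed = 2)
  expect_gte(fit$training_metrics$r2, 0.99)
})

test_that("a one-row grid equals a direct single fit", {
  m <- make_matrix(40, 8, seed = 6)
  rt <- 5 + m[, 2] + rnorm(40, 0, 0.2)
  grid <- data.frame(cost = 10, gamma = 0.05, epsilon = 0.1)
  fit <- fit_rt_model(m, rt, grid = grid, seed = 9)
  # direct oracle: same standardization + svm call outside the package path
  keep <- filter_descriptors(m)
  x <- scale(m[, keep, drop = FALSE])
  direct <- e1071::svm(x = x, y = rt, type = "eps-regression",
                       kernel = "radial", cost = 10, gamma = 0.05,
                       epsilon = 0.1, scale = FALSE)
  p1 <- predict_rt(fit, descriptors = m)$rt_pred
  p2 <- as.numeric(predict(direct, x))
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("conflicting duplicate structures leave irreducible residual", {
  m <- make_matrix(30, 6, seed = 7)
  m[30, ] <- m[29, ]                     # same structure twice
  rt <- c(seq(1, 15, length.out = 29), 0)
  rt[30] <- rt[29] + 4                   # measured 4 min apart
  fit <- fit_rt_model(m, rt, seed = 1)
  p <- predict_rt(fit, descriptors = m[29:30, , drop = FALSE])$rt_pred
  expect_equal(p[1], p[2], tolerance = 1e-8)
  expect_gte(max(abs(p - rt[29:30])), 2)  # at least half the 4-min gap
})

test_that("cross-validation is deterministic and order-invariant", {
  m <- make_matrix(60, 8, seed = 12)
  rt <- 4 + 1.5 * m[, 1] + rnorm(60, 0, 0.3)
  grid <- data.frame(cost = 10, gamma = NA, epsilon = 0.1)
  cv1 <- cross_validate_rt(m, rt, folds = 5, grid = grid, seed = 21)
  cv2 <- cross_validate_rt(m, rt, folds = 5, grid = grid, seed = 21)
  expect_identical(cv1[c("mean_r2", "mean_mae", "sd_mae")],
                   cv2[c("mean_r2", "mean_mae", "sd_mae")])
  # shuffled input rows, same seed: identical metrics
  set.seed(99); perm <- sample.int(60)
  cv3 <- cross_validate_rt(m[perm, ], rt[perm], folds = 5, grid = grid,
                           seed = 21)
  expect_equal(cv1[c("mean_r2", "mean_mae", "sd_mae")],
               cv3[c("mean_r2", "mean_mae", "sd_mae")], tolerance = 1e-10)
  # boundary folds: leave-one-out runs
  cv_loo <- cross_validate_rt(m[1:10, ], rt[1:10], folds = 10, grid = grid,
                              seed = 3)
  expect_equal(nrow(cv_loo$per_fold), 10)
  expect_error(cross_validate_rt(m[1:5, ], rt[1:5], folds = 6, grid = grid),
               "fold error")
})

test_that("cross-validated fit is never materially better than training", {
  pipe <- fx_pipeline()
  expect_lte(pipe$rt_cv$mean_r2, pipe$rt_model$training_metrics$r2 + 0.02)
})

test_that("training compounds are predicted at the training error scale", {
  pipe <- fx_pipeline()
  std <- pipe$measurements$standards
  d <- pipe$library$descriptors
  d[std$descriptor_incomplete, ] <- NA
  ts <- build_rt_training_set(std, descriptors = d)
  p <- predict_rt(pipe$rt_model, descriptors = ts$descriptors)
  resid <- abs(p$rt_pred - ts$rt)
  expect_lte(median(resid), pipe$rt_model$training_metrics$mae + 0.05)
})

test_that("out-of-range structures and bad input are flagged, not fatal", {
  pipe <- fx_pipeline()
  d <- pipe$library$descriptors[1:2, , drop = FALSE]
  d[2, ] <- d[2, ] * 50   # far outside every training descriptor range
  p <- predict_rt(pipe$rt_model, descriptors = d)
  expect_true(p$extrapolation_flag[2])
  p_bad <- predict_rt(pipe$rt_model, smiles = "not_a_smiles")
  expect_false(p_bad$ok[1])
  expect_true(is.na(p_bad$rt_pred[1]))
})

test_that("descriptor-incomplete compounds are excluded with a record", {
  pipe <- fx_pipeline()
  std <- pipe$measurements$standards
  d <- pipe$library$descriptors
  d[std$descriptor_incomplete, ] <- NA
  ts <- build_rt_training_set(std, descriptors = d)
  expect_setequal(ts$excluded, std$id[std$descriptor_incomplete])
  expect_equal(length(ts$rt), nrow(std) - sum(std$descriptor_incomplete))
})
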