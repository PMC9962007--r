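# Cluster-based CCS model: OLS oracle equivalence, determinism, adduct
# separation, monotone mass trend, batch bookkeeping, cluster-count
# selection.

make_ccs_fixture <- function(n = 80, seed = 31) {
  set.seed(seed)
  p <- 6
  desc <- matrix(rnorm(n * p), n, p,
                 dimnames = list(NULL, paste0("d", seq_len(p))))
  mz <- runif(n, 100, 800)
  adduct <- sample(c("[M+H]+", "[M-H]-"), n, replace = TRUE)
  ccs <- 30 + 9 * sqrt(mz) + 2 * desc[, 1] - desc[, 3] +
    ifelse(adduct == "[M+H]+", 0, -2) + rnorm(n, 0, 1)
  list(desc = desc, mz = mz, adduct = adduct, ccs = ccs)
}

test_that("k = 1 with the linear regressor matches the OLS oracle", {
  fx <- make_ccs_fixture()
  m <- fit_ccs_model(fx$desc, fx$mz, fx$adduct, fx$ccs, n_clusters = 1,
                     regressor = "linear", seed = 5)
  p <- predict_ccs_features(m, fx$desc, fx$mz, fx$adduct)$ccs_pred
  # independent oracle: closed-form least squares on the raw features
  # (OLS predictions are invariant to the affine standardization)
  onehot <- outer(fx$adduct, sort(unique(fx$adduct)), `==`) * 1
  X <- cbind(1, fx$desc, fx$mz, sqrt(fx$mz), onehot[, 1])
  beta <- qr.solve(crossprod(X), crossprod(X, fx$ccs))
  expect_equal(p, as.numeric(X %*% beta), tolerance = 1e-6)
})

test_that("fits and predictions are reproducible under a fixed seed", {
  fx <- make_ccs_fixture(n = 120, seed = 8)
  m1 <- fit_ccs_model(fx$desc, fx$mz, fx$adduct, fx$ccs, n_clusters = 3,
                      cost = 10, gamma = NA, epsilon = 0.05, seed = 17)
  m2 <- fit_ccs_model(fx$desc, fx$mz, fx$adduct, fx$ccs, n_clusters = 3,
                      cost = 10, gamma = NA, epsilon = 0.05, seed = 17)
  expect_identical(m1$cluster_sizes, m2$cluster_sizes)
  p1 <- predict_ccs_features(m1, fx$desc, fx$mz, fx$adduct)$ccs_pred
  p2 <- predict_ccs_features(m2, fx$desc, fx$mz, fx$adduct)$ccs_pred
  expect_identical(p1, p2)
})

test_that("different adducts of one metabolite get different CCS", {
  pipe <- fx_pipeline()
  rec <- pipe$library$records[1, ]
  d <- pipe$library$descriptors[1, , drop = FALSE]
  p1 <- predict_ccs_features(pipe$ccs_model, d,
                             adduct_mz(rec$neutral_mass, "[M+H]+"), "[M+H]+")
  p2 <- predict_ccs_features(pipe$ccs_model, d,
                             adduct_mz(rec$neutral_mass, "[M+Na]+"), "[M+Na]+")
  expect_false(isTRUE(all.equal(p1$ccs_pred, p2$ccs_pred)))
})

test_that("predicted CCS is non-decreasing along a homologous series", {
  pipe <- fx_pipeline()
  pool <- metabolite_pool()
  fa <- pool[grepl("^fatty_acid_C", pool$name), ][1:14, ]
  d <- compute_descriptors(fa$smiles)
  mass <- vapply(attr(d, "formula"), monoisotopic_mass, numeric(1))
  ord <- order(mass)
  p <- predict_ccs_features(pipe$ccs_model, d[ord, ],
                            adduct_mz(mass[ord], "[M-H]-"),
                            rep("[M-H]-", length(ord)))
  expect_true(all(diff(p$ccs_pred) > 0))
})

test_that("far-from-training entries raise the extrapolation flag", {
  fx <- make_ccs_fixture()
  m <- fit_ccs_model(fx$desc, fx$mz, fx$adduct, fx$ccs, n_clusters = 1,
                     cost = 10, gamma = NA, epsilon = 0.05, seed = 2)
  far <- fx$desc[1, , drop = FALSE] + 100
  p <- predict_ccs_features(m, far, 5000, "[M+H]+")
  expect_true(p$extrapolation_flag[1])
  expect_error(predict_ccs_features(m, fx$desc[1, , drop = FALSE], 100,
                                    "[M+K]+"), "adduct error")
})

test_that("underpopulated clusters trigger automatic k reduction", {
  fx <- make_ccs_fixture(n = 40, seed = 4)
  expect_message(
    m <- fit_ccs_model(fx$desc, fx$mz, fx$adduct, fx$ccs, n_clusters = 4,
                       cost = 10, gamma = NA, epsilon = 0.05,
                       min_cluster_size = 18, seed = 3),
    "reducing k")
  expect_lt(m$n_clusters, 4)
})

test_that("batch prediction keeps row cardinality and reject bookkeeping", {
  pipe <- fx_pipeline()
  mets <- data.frame(
    id = sprintf("X%02d", 1:5),
    smiles = c("CCO", "CCCCO", "not_a_smiles", "OC(=O)CCC(=O)O",
               "NCCc1ccc(O)cc1"),
    stringsAsFactors = FALSE)
  adducts <- c("[M+H]+", "[M-H]-")
  out <- batch_predict_ccs(pipe$ccs_model, mets, adducts)
  expect_equal(nrow(out$predictions), 4 * 2)
  expect_equal(out$rejects$id, "X03")
  # full cardinality with no failures
  ok <- mets[-3, , drop = FALSE]
  out2 <- batch_predict_ccs(pipe$ccs_model, ok, adducts)
  expect_equal(nrow(out2$predictions), nrow(ok) * length(adducts))
  expect_warning(out3 <- batch_predict_ccs(pipe$ccs_model, ok, character(0)),
                 "empty adduct list")
  expect_equal(nrow(out3$predictions), 0)
})

test_that("silhouette selection recovers three planted clusters", {
  ks <- vapply(1:5, function(s) {
    set.seed(100 + s)
    x <- rbind(matrix(rnorm(150, 0), ncol = 5),
               matrix(rnorm(150, 4), ncol = 5),
               matrix(rnorm(150, -4), ncol = 5))
    select_n_clusters(x, 2:8, seed = s)$k
  }, integer(1))
  expect_gte(sum(ks == 3L), 3)  # majority of seeds
})
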