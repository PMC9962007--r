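# Cluster-based CCS prediction: centroid clustering of standardized
# (descriptors + m/z + adduct one-hot) features with one kernel regressor
# per cluster, in the architecture class of cluster-regression CCS
# predictors.

#' Build the CCS feature matrix
#'
#' Descriptors (filtered columns) augmented with m/z and a one-hot encoding
#' of the adduct label; the adduct encoding carries polarity, so positive
#' and negative modes are modelled jointly.
#'
#' @param descriptors Descriptor matrix (rows aligned with \code{mz} /
#'   \code{adduct}).
#' @param mz m/z values (Th).
#' @param adduct Adduct labels.
#' @param adduct_levels Complete set of adduct labels the encoding must
#'   cover (defaults to the observed set, sorted).
#' @return Numeric feature matrix.
#' @keywords internal
.ccs_features <- function(descriptors, mz, adduct,
                          adduct_levels = sort(unique(adduct))) {
  adduct <- normalize_adduct(adduct)
  bad <- setdiff(unique(adduct), adduct_levels)
  if (length(bad) > 0L) {
    stop("adduct error: adduct(s) not in model's supported set: ",
         paste(bad, collapse = ", "))
  }
  onehot <- outer(adduct, adduct_levels, `==`) * 1
  colnames(onehot) <- paste0("adduct_", adduct_levels)
  # CCS grows roughly with the square root of the ion mass, so sqrt(m/z)
  # is supplied alongside m/z as an explicit feature
  cbind(descriptors, mz = mz, sqrt_mz = sqrt(mz), onehot)
}

#' Select the number of clusters by mean silhouette width
#'
#' Runs seeded k-means for each candidate k and returns the k with the
#' largest mean silhouette width.
#'
#' @param x Standardized feature matrix.
#' @param krange Candidate cluster counts (all >= 2).
#' @param seed Integer seed.
#' @param nstart k-means restarts.
#' @return List with \code{k} (the winner) and \code{widths} (named mean
#'   silhouette width per candidate).
#' @export
select_n_clusters <- function(x, krange = 2:8, seed = 1L, nstart = 10L) {
  stopifnot(all(krange >= 2L), nrow(x) > max(krange))
  d <- stats::dist(x)
  widths <- vapply(krange, function(k) {
    set.seed(seed)
    km <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 50L)
    mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
  }, numeric(1L))
  names(widths) <- krange
  list(k = krange[which.max(widths)], widths = widths)
}

.fit_cluster_regressor <- function(x, y, regressor, cost, gamma, epsilon) {
  if (regressor == "linear") {
    # ordinary least squares on the standardized features
    fit <- stats::lm.fit(cbind(1, x), y)
    list(kind = "linear", coef = fit$coefficients)
  } else {
    # the response is standardized inside the cluster so the epsilon tube
    # and cost are on a unit scale regardless of the CCS magnitude
    y_ctr <- mean(y)
    y_scl <- stats::sd(y)
    if (!is.finite(y_scl) || y_scl == 0) y_scl <- 1
    list(kind = "svr",
         fit = .fit_svr(x, (y - y_ctr) / y_scl, cost, gamma, epsilon),
         y_ctr = y_ctr, y_scl = y_scl)
  }
}

.predict_cluster_regressor <- function(reg, x) {
  if (reg$kind == "linear") {
    beta <- reg$coef
    beta[is.na(beta)] <- 0
    as.numeric(cbind(1, x) %*% beta)
  } else {
    as.numeric(stats::predict(reg$fit, x)) * reg$y_scl + reg$y_ctr
  }
}

#' Fit the cluster-based CCS model
#'
#' Standardizes the feature matrix (descriptors + m/z + adduct one-hot),
#' partitions the training entries by seeded k-means, and fits one
#' regressor per cluster. Clusters that fall below the minimum occupancy
#' trigger an automatic reduction of \code{n_clusters} (logged via a
#' message); a single global regressor is the k = 1 degenerate case.
#'
#' @param descriptors Descriptor matrix, one row per training entry
#'   (compound repeated across its adducts).
#' @param mz m/z of each entry (Th).
#' @param adduct Adduct label of each entry.
#' @param ccs Measured CCS of each entry (Å², > 0).
#' @param n_clusters Integer k, or \code{"auto"} to select by silhouette
#'   over \code{krange}.
#' @param krange Candidate k values for \code{"auto"}.
#' @param regressor \code{"svr"} (radial kernel, default) or
#'   \code{"linear"} (per-cluster least squares).
#' @param cost,gamma,epsilon SVR hyperparameters (\code{gamma = NA} uses
#'   e1071's 1/p default). Vectors define a grid searched by seeded
#'   internal cross-validation of a global regressor before the per-cluster
#'   fits.
#' @param min_cluster_size Minimum training entries per cluster.
#' @param nzv_threshold,cor_threshold Descriptor filtering thresholds.
#' @param seed Integer seed; clustering and fits are reproducible given it.
#' @return An object of class \code{ccs_model}.
#' @export
fit_ccs_model <- function(descriptors, mz, adduct, ccs,
                          n_clusters = "auto", krange = 2:8,
                          regressor = c("svr", "linear"),
                          cost = c(1, 10, 100), gamma = c(NA, 0.02, 0.002),
                          epsilon = 0.05,
                          min_cluster_size = 15L,
                          nzv_threshold = 1e-8, cor_threshold = 0.95,
                          seed = 1L) {
  regressor <- match.arg(regressor)
  stopifnot(is.matrix(descriptors),
            length(mz) == nrow(descriptors),
            length(adduct) == nrow(descriptors),
            length(ccs) == nrow(descriptors))
  if (any(!is.finite(ccs)) || any(ccs <= 0)) {
    stop("measured CCS must be finite and > 0")
  }
  complete <- rowSums(is.na(descriptors)) == 0L & is.finite(mz)
  if (!all(complete)) {
    message(sum(!complete), " entries excluded for incomplete descriptors")
  }
  descriptors <- descriptors[complete, , drop = FALSE]
  mz <- mz[complete]; adduct <- normalize_adduct(adduct[complete])
  ccs <- ccs[complete]
  adduct_levels <- sort(unique(adduct))
  keep <- filter_descriptors(descriptors, nzv_threshold, cor_threshold)
  feats <- .ccs_features(descriptors[, keep, drop = FALSE], mz, adduct,
                         adduct_levels)
  sc <- .standardize_fit(feats)
  xs <- .standardize_apply(feats, sc)

  # hyperparameter grid resolved once, by seeded internal CV of a global
  # regressor on the standardized response, then shared by all clusters
  if (regressor == "svr" &&
      (length(cost) > 1L || length(gamma) > 1L || length(epsilon) > 1L)) {
    grid <- expand.grid(cost = cost, gamma = gamma, epsilon = epsilon,
                        KEEP.OUT.ATTRS = FALSE)
    y_sc <- (ccs - mean(ccs)) / stats::sd(ccs)
    fold_id <- .make_folds(length(ccs), 3L, seed)
    cv_mae <- vapply(seq_len(nrow(grid)), function(g) {
      errs <- vapply(sort(unique(fold_id)), function(k) {
        trn <- fold_id != k
        fit <- .fit_svr(xs[trn, , drop = FALSE], y_sc[trn],
                        grid$cost[g], grid$gamma[g], grid$epsilon[g])
        mean(abs(stats::predict(fit, xs[!trn, , drop = FALSE]) - y_sc[!trn]))
      }, numeric(1L))
      mean(errs)
    }, numeric(1L))
    best <- grid[which.min(cv_mae), ]
    cost <- best$cost; gamma <- best$gamma; epsilon <- best$epsilon
  }

  if (identical(n_clusters, "auto")) {
    krange <- krange[krange * 10L <= nrow(xs)]
    n_clusters <- if (length(krange) == 0L) 1L else {
      select_n_clusters(xs, krange, seed = seed)$k
    }
  }
  n_clusters <- as.integer(n_clusters)
  if (nrow(xs) < 10L * n_clusters) {
    stop("insufficient-data error: need >= 10 entries per requested cluster")
  }

  repeat {
    if (n_clusters == 1L) {
      assign <- rep(1L, nrow(xs))
      centers <- matrix(colMeans(xs), 1L, ncol(xs),
                        dimnames = list(NULL, colnames(xs)))
      break
    }
    set.seed(seed)
    km <- stats::kmeans(xs, centers = n_clusters, nstart = 10L,
                        iter.max = 50L)
    if (min(table(km$cluster)) >= min_cluster_size) {
      assign <- km$cluster
      centers <- km$centers
      break
    }
    message("cluster below minimum occupancy; reducing k to ",
            n_clusters - 1L)
    n_clusters <- n_clusters - 1L
  }

  regs <- vector("list", n_clusters)
  max_dist <- numeric(n_clusters)
  for (k in seq_len(n_clusters)) {
    in_k <- assign == k
    regs[[k]] <- .fit_cluster_regressor(xs[in_k, , drop = FALSE], ccs[in_k],
                                        regressor, cost, gamma, epsilon)
    d <- sqrt(rowSums(sweep(xs[in_k, , drop = FALSE], 2L, centers[k, ])^2))
    max_dist[k] <- max(d)
  }
  pred <- predict_ccs_features(
    structure(list(selected = colnames(descriptors)[keep], scaler = sc,
                   centers = centers, regressors = regs,
                   max_dist = max_dist, adduct_levels = adduct_levels),
              class = "ccs_model"),
    descriptors[, , drop = FALSE], mz, adduct)$ccs_pred
  structure(list(
    selected = colnames(descriptors)[keep],
    scaler = sc,
    centers = centers,
    regressors = regs,
    max_dist = max_dist,
    adduct_levels = adduct_levels,
    n_clusters = n_clusters,
    regressor = regressor,
    hyper = list(cost = cost, gamma = gamma, epsilon = epsilon),
    cluster_sizes = as.integer(table(assign)),
    training_metrics = list(mae = mean(abs(pred - ccs)),
                            r2 = 1 - sum((ccs - pred)^2) /
                              sum((ccs - mean(ccs))^2)),
    seed = seed
  ), class = "ccs_model")
}

#' @export
print.ccs_model <- function(x, ...) {
  cat("Cluster-based CCS model\n")
  cat(sprintf("  clusters: %d (sizes: %s), regressor: %s\n", x$n_clusters,
              paste(x$cluster_sizes, collapse = ", "), x$regressor))
  cat(sprintf("  features: %d descriptors + m/z + %d adduct indicators\n",
              length(x$selected), length(x$adduct_levels)))
  cat(sprintf("  training MAE=%.2f A^2, R2=%.3f\n",
              x$training_metrics$mae, x$training_metrics$r2))
  invisible(x)
}

#' Predict CCS from a descriptor matrix
#'
#' Vectorised prediction: each entry is assigned to its nearest cluster
#' center and scored by that cluster's regressor. The extrapolation flag is
#' set when the distance to the nearest center exceeds the largest training
#' distance seen in that cluster.
#'
#' @param model A \code{ccs_model}.
#' @param descriptors Descriptor matrix with the full panel columns.
#' @param mz m/z per row.
#' @param adduct Adduct label per row (must be in the model's supported
#'   set).
#' @return data.frame with \code{ccs_pred} (Å²), \code{cluster},
#'   \code{extrapolation_flag}, \code{ok}.
#' @export
predict_ccs_features <- function(model, descriptors, mz, adduct) {
  stopifnot(inherits(model, "ccs_model"))
  adduct <- normalize_adduct(adduct)
  bad <- setdiff(unique(adduct), model$adduct_levels)
  if (length(bad) > 0L) {
    stop("adduct error: unsupported adduct(s): ", paste(bad, collapse = ", "))
  }
  missing_cols <- setdiff(model$selected, colnames(descriptors))
  if (length(missing_cols) > 0L) {
    stop("descriptor matrix lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  x <- descriptors[, model$selected, drop = FALSE]
  ok <- rowSums(is.na(x)) == 0L & is.finite(mz)
  n <- nrow(x)
  out <- data.frame(ccs_pred = rep(NA_real_, n), cluster = rep(NA_integer_, n),
                    extrapolation_flag = rep(NA, n), ok = ok,
                    row.names = NULL)
  if (!any(ok)) return(out)
  feats <- .ccs_features(x[ok, , drop = FALSE], mz[ok], adduct[ok],
                         model$adduct_levels)
  xs <- .standardize_apply(feats, model$scaler)
  dists <- vapply(seq_len(nrow(model$centers)), function(k) {
    rowSums(sweep(xs, 2L, model$centers[k, ])^2)
  }, numeric(nrow(xs)))
  dists <- matrix(dists, nrow = nrow(xs))
  nearest <- max.col(-dists, ties.method = "first")
  pred <- numeric(nrow(xs))
  flag <- logical(nrow(xs))
  for (k in sort(unique(nearest))) {
    in_k <- nearest == k
    pred[in_k] <- .predict_cluster_regressor(model$regressors[[k]],
                                             xs[in_k, , drop = FALSE])
    flag[in_k] <- sqrt(dists[in_k, k]) > model$max_dist[k]
  }
  out$ccs_pred[ok] <- pred
  out$cluster[ok] <- nearest
  out$extrapolation_flag[ok] <- flag
  out
}

#' Predict CCS for one metabolite and adduct
#'
#' @param model A \code{ccs_model}.
#' @param smiles Structure string of the metabolite.
#' @param adduct Adduct label.
#' @param neutral_mass Optional neutral monoisotopic mass (Da); derived
#'   from the structure's formula when omitted.
#' @return One-row data.frame as \code{\link{predict_ccs_features}}.
#' @export
predict_ccs <- function(model, smiles, adduct, neutral_mass = NULL) {
  d <- compute_descriptors(smiles)
  if (is.null(neutral_mass)) {
    f <- attr(d, "formula")[1L]
    if (is.na(f)) {
      return(data.frame(ccs_pred = NA_real_, cluster = NA_integer_,
                        extrapolation_flag = NA, ok = FALSE))
    }
    neutral_mass <- monoisotopic_mass(f)
  }
  predict_ccs_features(model, d, adduct_mz(neutral_mass, adduct), adduct)
}

#' Batch CCS prediction over a candidate table
#'
#' Processes candidates in bounded-memory chunks; every (candidate, adduct)
#' combination yields one row, and candidates whose structures fail yield
#' reject records rather than rows.
#'
#' @param model A \code{ccs_model}.
#' @param metabolites data.frame with columns \code{id} and \code{smiles}.
#' @param adducts Character vector of adduct labels to predict (defaults to
#'   the model's supported set).
#' @param chunk_size Candidates per chunk.
#' @return List: \code{predictions} (data.frame id, adduct, mz, ccs_pred_A2,
#'   extrapolation_flag) and \code{rejects} (data.frame id, reason).
#' @export
batch_predict_ccs <- function(model, metabolites,
                              adducts = model$adduct_levels,
                              chunk_size = 1000L) {
  stopifnot(all(c("id", "smiles") %in% names(metabolites)))
  if (length(adducts) == 0L) {
    warning("empty adduct list: no predictions generated")
    return(list(predictions = data.frame(id = character(), adduct = character(),
                                         mz = numeric(), ccs_pred_A2 = numeric(),
                                         extrapolation_flag = logical()),
                rejects = data.frame(id = character(), reason = character())))
  }
  adducts <- normalize_adduct(adducts)
  chunks <- split(seq_len(nrow(metabolites)),
                  ceiling(seq_len(nrow(metabolites)) / chunk_size))
  preds <- list(); rejects <- list()
  for (ch in chunks) {
    sub <- metabolites[ch, , drop = FALSE]
    d <- compute_descriptors(sub$smiles)
    formulas <- attr(d, "formula")
    usable <- attr(d, "parsed") & !is.na(formulas)
    if (any(!usable)) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        id = sub$id[!usable], reason = "unparseable structure")
    }
    # rows whose descriptors exist but are incomplete for the model
    incomplete <- usable &
      rowSums(is.na(d[, model$selected, drop = FALSE])) > 0L
    if (any(incomplete)) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        id = sub$id[incomplete], reason = "incomputable descriptors")
      usable <- usable & !incomplete
    }
    if (!any(usable)) next
    idx <- which(usable)
    mass <- vapply(formulas[idx], monoisotopic_mass, numeric(1L))
    grid <- expand.grid(row = idx, adduct = adducts,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mz <- adduct_mz(mass[match(grid$row, idx)], grid$adduct)
    p <- predict_ccs_features(model, d[grid$row, , drop = FALSE], mz,
                              grid$adduct)
    preds[[length(preds) + 1L]] <- data.frame(
      id = sub$id[grid$row],
      adduct = grid$adduct, mz = mz, ccs_pred_A2 = p$ccs_pred,
      extrapolation_flag = p$extrapolation_flag,
      stringsAsFactors = FALSE)
  }
  list(
    predictions = if (length(preds)) do.call(rbind, preds) else
      data.frame(id = character(), adduct = character(), mz = numeric(),
                 ccs_pred_A2 = numeric(), extrapolation_flag = logical()),
    rejects = if (length(rejects)) do.call(rbind, rejects) else
      data.frame(id = character(), reason = character())
  )
}
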