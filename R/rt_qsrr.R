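# QSRR retention-time model: descriptor filtering, seeded grid-searched
# support-vector regression, k-fold cross-validation, prediction with
# extrapolation flagging.

#' Default SVR hyperparameter grid for the retention-time model
#'
#' @param cost Regularization constants to try.
#' @param gamma Radial-kernel widths; \code{NA} means e1071's 1/p default.
#' @param epsilon Epsilon-insensitive tube widths.
#' @return data.frame, one row per hyperparameter combination.
#' @export
rt_default_grid <- function(cost = c(1, 10, 100),
                            gamma = c(NA, 0.01, 0.1),
                            epsilon = c(0.1)) {
  expand.grid(cost = cost, gamma = gamma, epsilon = epsilon,
              KEEP.OUT.ATTRS = FALSE)
}

#' Filter a descriptor matrix
#'
#' Drops, in order: descriptors with any missing value, descriptors with
#' near-zero variance, then one of each highly correlated pair (the
#' later-indexed column is dropped so the result is deterministic).
#'
#' @param mat Numeric matrix, compounds x descriptors.
#' @param nzv_threshold Variance below which a descriptor is dropped.
#' @param cor_threshold Absolute pairwise correlation above which the
#'   later-indexed descriptor of the pair is dropped.
#' @return Integer vector of retained column indices (increasing).
#' @export
filter_descriptors <- function(mat, nzv_threshold = 1e-8,
                               cor_threshold = 0.95) {
  if (!is.matrix(mat) || nrow(mat) == 0L || ncol(mat) == 0L) {
    stop("degenerate-input error: empty descriptor matrix")
  }
  keep <- which(colSums(is.na(mat)) == 0L)
  if (length(keep) > 0L) {
    v <- apply(mat[, keep, drop = FALSE], 2L, stats::var)
    keep <- keep[v >= nzv_threshold & is.finite(v)]
  }
  if (length(keep) > 1L) {
    cm <- abs(suppressWarnings(stats::cor(mat[, keep, drop = FALSE])))
    cm[is.na(cm)] <- 0
    dropped <- logical(length(keep))
    for (i in seq_along(keep)) {
      if (dropped[i]) next
      j <- which(cm[i, ] > cor_threshold)
      dropped[j[j > i]] <- TRUE
    }
    keep <- keep[!dropped]
  }
  if (length(keep) == 0L) {
    stop("degenerate-input error: all descriptors eliminated")
  }
  keep
}

.standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

.standardize_apply <- function(x, sc) {
  sweep(sweep(x, 2L, sc$center, "-"), 2L, sc$scale, "/")
}

.fit_svr <- function(x, y, cost, gamma, epsilon) {
  args <- list(x = x, y = y, type = "eps-regression", kernel = "radial",
               cost = cost, epsilon = epsilon, scale = FALSE)
  if (!is.na(gamma)) args$gamma <- gamma
  do.call(e1071::svm, args)
}

# Seeded fold assignment shared by grid search and cross-validation.
.make_folds <- function(n, folds, seed) {
  if (folds < 2L) stop("fold error: folds must be >= 2")
  if (folds > n) stop("fold error: more folds than compounds")
  set.seed(seed)
  idx <- sample.int(n)
  rep_len(seq_len(folds), n)[order(idx)]
}

.grid_search_svr <- function(x, y, grid, inner_folds, seed) {
  if (nrow(grid) == 1L) return(grid[1L, , drop = FALSE])
  fold_id <- .make_folds(length(y), min(inner_folds, length(y)), seed)
  cv_mae <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(sort(unique(fold_id)), function(k) {
      tr <- fold_id != k
      fit <- .fit_svr(x[tr, , drop = FALSE], y[tr],
                      grid$cost[g], grid$gamma[g], grid$epsilon[g])
      mean(abs(stats::predict(fit, x[!tr, , drop = FALSE]) - y[!tr]))
    }, numeric(1L))
    mean(errs)
  }, numeric(1L))
  grid[which.min(cv_mae), , drop = FALSE]
}

#' Fit the QSRR retention-time model
#'
#' Filters and standardizes the descriptor matrix, selects radial-kernel SVR
#' hyperparameters by seeded internal cross-validation over a grid, and
#' refits the winning configuration on the full training set. Compounds with
#' missing descriptors must be excluded beforehand (see
#' \code{\link{build_rt_training_set}}).
#'
#' @param descriptors Numeric matrix, compounds x descriptors (no NA in
#'   retained columns).
#' @param rt Measured retention times in minutes, one per compound.
#' @param grid Hyperparameter grid (\code{\link{rt_default_grid}}); a
#'   one-row grid skips the search.
#' @param nzv_threshold,cor_threshold Passed to
#'   \code{\link{filter_descriptors}}.
#' @param inner_folds Folds for the internal grid-search CV.
#' @param run_length Chromatographic run length in minutes (prediction
#'   window for extrapolation flagging).
#' @param seed Integer seed; the fit is fully reproducible given it.
#' @return An object of class \code{rt_model}.
#' @export
fit_rt_model <- function(descriptors, rt, grid = rt_default_grid(),
                         nzv_threshold = 1e-8, cor_threshold = 0.95,
                         inner_folds = 5L, run_length = 17, seed = 1L) {
  stopifnot(is.matrix(descriptors), length(rt) == nrow(descriptors))
  if (nrow(descriptors) < 20L) {
    stop("insufficient-data error: need >= 20 training compounds, got ",
         nrow(descriptors))
  }
  keep <- filter_descriptors(descriptors, nzv_threshold, cor_threshold)
  x <- descriptors[, keep, drop = FALSE]
  sc <- .standardize_fit(x)
  xs <- .standardize_apply(x, sc)
  best <- .grid_search_svr(xs, rt, grid, inner_folds, seed)
  fit <- .fit_svr(xs, rt, best$cost, best$gamma, best$epsilon)
  pred <- as.numeric(stats::predict(fit, xs))
  r2 <- 1 - sum((rt - pred)^2) / sum((rt - mean(rt))^2)
  structure(list(
    selected = colnames(descriptors)[keep],
    scaler = sc,
    fit = fit,
    hyper = as.list(best),
    train_range = apply(xs, 2L, range),
    run_length = run_length,
    training_metrics = list(r2 = r2, mae = mean(abs(rt - pred))),
    cv_metrics = NULL,
    seed = seed
  ), class = "rt_model")
}

#' @export
print.rt_model <- function(x, ...) {
  cat("QSRR retention-time model (radial SVR)\n")
  cat(sprintf("  descriptors: %d retained\n", length(x$selected)))
  cat(sprintf("  hyperparameters: cost=%g gamma=%s epsilon=%g\n",
              x$hyper$cost, ifelse(is.na(x$hyper$gamma), "1/p",
                                   format(x$hyper$gamma)), x$hyper$epsilon))
  cat(sprintf("  training R2=%.3f MAE=%.3f min\n",
              x$training_metrics$r2, x$training_metrics$mae))
  if (!is.null(x$cv_metrics)) {
    cat(sprintf("  CV mean R2=%.3f mean MAE=%.3f min (SD %.3f)\n",
                x$cv_metrics$mean_r2, x$cv_metrics$mean_mae,
                x$cv_metrics$sd_mae))
  }
  invisible(x)
}

#' Cross-validate the QSRR retention-time model
#'
#' Seeded shuffle, k-fold split, and a full refit per fold (descriptor
#' filtering, standardization and the hyperparameter search all happen
#' inside the fold, so held-out metrics carry no leakage).
#'
#' @inheritParams fit_rt_model
#' @param folds Number of folds (>= 2, <= number of compounds).
#' @return List with \code{mean_r2}, \code{mean_mae} (min), \code{sd_mae}
#'   (SD of per-fold MAE, min), and per-fold tables.
#' @export
cross_validate_rt <- function(descriptors, rt, folds = 10L,
                              grid = rt_default_grid(),
                              nzv_threshold = 1e-8, cor_threshold = 0.95,
                              inner_folds = 3L, seed = 1L) {
  stopifnot(is.matrix(descriptors), length(rt) == nrow(descriptors))
  # canonical row order first, so fold membership depends on content (and
  # the seed), not on the order rows arrived in
  canon <- do.call(order, c(list(rt), lapply(seq_len(ncol(descriptors)),
                                             function(j) descriptors[, j])))
  descriptors <- descriptors[canon, , drop = FALSE]
  rt <- rt[canon]
  n <- nrow(descriptors)
  fold_id <- .make_folds(n, folds, seed)
  per_fold <- lapply(sort(unique(fold_id)), function(k) {
    tr <- fold_id != k
    keep <- filter_descriptors(descriptors[tr, , drop = FALSE],
                               nzv_threshold, cor_threshold)
    xtr <- descriptors[tr, keep, drop = FALSE]
    sc <- .standardize_fit(xtr)
    xs <- .standardize_apply(xtr, sc)
    best <- .grid_search_svr(xs, rt[tr], grid, inner_folds, seed + k)
    fit <- .fit_svr(xs, rt[tr], best$cost, best$gamma, best$epsilon)
    xte <- .standardize_apply(descriptors[!tr, keep, drop = FALSE], sc)
    pred <- as.numeric(stats::predict(fit, xte))
    obs <- rt[!tr]
    ss_tot <- sum((obs - mean(obs))^2)
    data.frame(
      fold = k,
      n_test = length(obs),
      mae = mean(abs(pred - obs)),
      r2 = if (ss_tot > 0) 1 - sum((obs - pred)^2) / ss_tot else NA_real_
    )
  })
  per_fold <- do.call(rbind, per_fold)
  list(
    mean_r2 = mean(per_fold$r2, na.rm = TRUE),
    mean_mae = mean(per_fold$mae),
    sd_mae = stats::sd(per_fold$mae),
    folds = folds,
    per_fold = per_fold
  )
}

#' Predict retention time for structures
#'
#' Computes descriptors (or takes a precomputed matrix), applies the model's
#' stored descriptor selection and scaling, and predicts Rt. The
#' extrapolation flag is set when any scaled descriptor falls outside the
#' training range or the prediction falls outside the chromatographic
#' window; predictions for structures whose required descriptors cannot be
#' computed are returned as \code{NA} with \code{ok = FALSE}, never as a
#' crash.
#'
#' @param model An \code{rt_model}.
#' @param smiles Character vector of structures (ignored when
#'   \code{descriptors} is given).
#' @param descriptors Optional precomputed descriptor matrix with the full
#'   panel columns.
#' @return data.frame with \code{rt_pred} (min), \code{extrapolation_flag},
#'   \code{ok}.
#' @export
predict_rt <- function(model, smiles = NULL, descriptors = NULL) {
  stopifnot(inherits(model, "rt_model"))
  if (is.null(descriptors)) {
    if (is.null(smiles)) stop("supply smiles or descriptors")
    descriptors <- compute_descriptors(smiles)
  }
  missing_cols <- setdiff(model$selected, colnames(descriptors))
  if (length(missing_cols) > 0L) {
    stop("descriptor matrix lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  x <- descriptors[, model$selected, drop = FALSE]
  ok <- rowSums(is.na(x)) == 0L
  n <- nrow(x)
  rt_pred <- rep(NA_real_, n)
  flag <- rep(NA, n)
  if (any(ok)) {
    xs <- .standardize_apply(x[ok, , drop = FALSE], model$scaler)
    rt_pred[ok] <- as.numeric(stats::predict(model$fit, xs))
    lo <- model$train_range[1L, ]
    hi <- model$train_range[2L, ]
    outside <- rowSums(sweep(xs, 2L, lo, "<") | sweep(xs, 2L, hi, ">")) > 0L
    flag[ok] <- outside | rt_pred[ok] < 0 | rt_pred[ok] > model$run_length
  }
  data.frame(rt_pred = rt_pred, extrapolation_flag = flag, ok = ok,
             row.names = NULL)
}

#' Assemble a retention-time training set from a standards table
#'
#' One Rt row per metabolite (Rt is adduct- and mode-independent): rows
#' duplicated across ionization modes are collapsed to their mean Rt with a
#' warning when the modes disagree. Compounds with any missing descriptor
#' are excluded (and listed), mirroring the exclusion of
#' descriptor-incomplete compounds before modelling.
#'
#' @param standards data.frame with columns \code{id}, \code{smiles},
#'   \code{rt_min} (a \code{mode} column, if present, is collapsed over).
#' @param descriptors Optional precomputed descriptor matrix with rows in
#'   \code{standards} order (one row per input row).
#' @param rt_disagreement_tol Warn when per-mode Rt of one metabolite differ
#'   by more than this many minutes.
#' @return List: \code{descriptors} (complete rows only), \code{rt},
#'   \code{ids}, \code{excluded} (ids dropped for missing descriptors).
#' @export
build_rt_training_set <- function(standards, descriptors = NULL,
                                  rt_disagreement_tol = 0.2) {
  stopifnot(all(c("id", "smiles", "rt_min") %in% names(standards)))
  agg <- stats::aggregate(rt_min ~ id, data = standards, FUN = mean)
  spread <- stats::aggregate(rt_min ~ id, data = standards,
                             FUN = function(v) diff(range(v)))
  if (any(spread$rt_min > rt_disagreement_tol)) {
    warning("Rt disagreement across modes for: ",
            paste(spread$id[spread$rt_min > rt_disagreement_tol],
                  collapse = ", "), " (mean used)")
  }
  first_idx <- match(agg$id, standards$id)
  if (is.null(descriptors)) {
    descriptors <- compute_descriptors(standards$smiles[first_idx])
  } else {
    stopifnot(nrow(descriptors) == nrow(standards))
    descriptors <- descriptors[first_idx, , drop = FALSE]
  }
  complete <- rowSums(is.na(descriptors)) == 0L
  list(
    descriptors = descriptors[complete, , drop = FALSE],
    rt = agg$rt_min[complete],
    ids = agg$id[complete],
    excluded = agg$id[!complete]
  )
}
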