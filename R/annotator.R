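# Matching of untargeted features against the annotation database under
# m/z-only and m/z + CCS + Rt strategies, hit statistics, and candidate
# ranking.

#' Define a match strategy
#'
#' Strategy 1 of the identification workflow is m/z-only (5 mDa default
#' tolerance); strategy 2 adds the CCS and Rt windows derived by the
#' calibration stage (16 Å² and 1.1 min by default).
#'
#' @param mz_tol Absolute m/z tolerance in Th (> 0).
#' @param use_ccs,use_rt Enable the CCS / Rt dimensions.
#' @param ccs_tol CCS tolerance in Å² (> 0).
#' @param rt_tol Rt tolerance in min (> 0).
#' @param missing_dim What to do when a feature lacks a value for an
#'   enabled dimension: \code{"pass"} (dimension skipped for that feature,
#'   flagged) or \code{"fail"} (feature cannot hit).
#' @return An object of class \code{match_strategy}.
#' @export
match_strategy <- function(mz_tol = 0.005, use_ccs = FALSE, ccs_tol = 16,
                           use_rt = FALSE, rt_tol = 1.1,
                           missing_dim = c("pass", "fail")) {
  stopifnot(mz_tol > 0, ccs_tol > 0, rt_tol > 0)
  structure(list(mz_tol = mz_tol, use_ccs = use_ccs, ccs_tol = ccs_tol,
                 use_rt = use_rt, rt_tol = rt_tol,
                 missing_dim = match.arg(missing_dim)),
            class = "match_strategy")
}

# Hits of one feature against db rows already restricted to its polarity
# and m/z window; returns a data.frame of per-dimension errors.
.score_hits <- function(feature, rows, strategy) {
  dmz <- rows$mz - feature$mz
  keep <- abs(dmz) <= strategy$mz_tol
  dccs <- rep(NA_real_, nrow(rows))
  drt <- rep(NA_real_, nrow(rows))
  norm_terms <- abs(dmz) / strategy$mz_tol
  n_dims <- rep(1, nrow(rows))
  if (strategy$use_ccs) {
    f_ccs <- feature$ccs_A2
    if (!is.null(f_ccs) && length(f_ccs) == 1L && is.finite(f_ccs)) {
      dccs <- rows$ccs_A2 - f_ccs
      keep <- keep & abs(dccs) <= strategy$ccs_tol
      norm_terms <- norm_terms + abs(dccs) / strategy$ccs_tol
      n_dims <- n_dims + 1
    } else if (strategy$missing_dim == "fail") {
      keep <- keep & FALSE
    }
  }
  if (strategy$use_rt) {
    f_rt <- feature$rt_min
    if (!is.null(f_rt) && length(f_rt) == 1L && is.finite(f_rt)) {
      drt <- rows$rt_min - f_rt
      keep <- keep & abs(drt) <= strategy$rt_tol
      norm_terms <- norm_terms + abs(drt) / strategy$rt_tol
      n_dims <- n_dims + 1
    } else if (strategy$missing_dim == "fail") {
      keep <- keep & FALSE
    }
  }
  data.frame(
    metabolite_id = rows$metabolite_id[keep],
    adduct = rows$adduct[keep],
    dmz = dmz[keep], dccs = dccs[keep], drt = drt[keep],
    score = (norm_terms / n_dims)[keep],
    stringsAsFactors = FALSE)
}

#' Match one feature against the database
#'
#' A database row is a hit iff the m/z error is within \code{mz_tol} and,
#' for each enabled dimension the feature carries, the CCS / Rt error is
#' within its window (boundaries inclusive). Polarity must match. Features
#' lacking a value for an enabled dimension are handled per the strategy's
#' \code{missing_dim} policy and flagged with a warning.
#'
#' @param feature One-row data.frame (or list) with \code{mz},
#'   \code{polarity} and optionally \code{rt_min}, \code{ccs_A2}.
#' @param db Database data.frame (see \code{\link{build_database}}).
#' @param strategy A \code{\link{match_strategy}}.
#' @return data.frame of hits with per-dimension signed errors and the
#'   normalized-error score.
#' @export
match_feature <- function(feature, db, strategy) {
  rows <- db[db$polarity == feature$polarity, , drop = FALSE]
  if ((strategy$use_ccs && !isTRUE(is.finite(feature$ccs_A2))) ||
      (strategy$use_rt && !isTRUE(is.finite(feature$rt_min)))) {
    warning("feature lacks a value for an enabled dimension (policy: ",
            strategy$missing_dim, ")")
  }
  .score_hits(feature, rows, strategy)
}

#' Annotate an untargeted feature table
#'
#' Applies \code{\link{match_feature}} to every feature, using an m/z-sorted
#' index with binary search to restrict candidate rows before the full
#' window test, and aggregates the hit-count distribution.
#'
#' @param features data.frame with \code{feature_id}, \code{mz},
#'   \code{polarity}, and optionally \code{rt_min}, \code{ccs_A2},
#'   \code{intensity}.
#' @param db Database data.frame.
#' @param strategy A \code{\link{match_strategy}}.
#' @return An object of class \code{annotation_report}: \code{hits}
#'   (per-feature hit rows), \code{per_feature} (feature_id, n_hits),
#'   \code{n_features}, \code{n_features_with_hits}, \code{total_hits},
#'   \code{bins} (features by hit count: 0, 1, 2-10, >10), and the strategy.
#' @export
annotate_table <- function(features, db, strategy) {
  stopifnot(all(c("feature_id", "mz", "polarity") %in% names(features)))
  ord <- order(db$mz)
  db_sorted <- db[ord, , drop = FALSE]
  hits <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    f <- features[i, , drop = FALSE]
    lo <- findInterval(f$mz - strategy$mz_tol, db_sorted$mz) + 1L
    hi <- findInterval(f$mz + strategy$mz_tol, db_sorted$mz)
    if (hi < lo) {
      hits[[i]] <- NULL
      next
    }
    cand <- db_sorted[lo:hi, , drop = FALSE]
    cand <- cand[cand$polarity == f$polarity, , drop = FALSE]
    h <- .score_hits(f, cand, strategy)
    if (nrow(h) > 0L) {
      h <- cbind(feature_id = f$feature_id, h, stringsAsFactors = FALSE)
      hits[[i]] <- h
    }
  }
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1L))])
  if (is.null(hits)) {
    hits <- data.frame(feature_id = character(), metabolite_id = character(),
                       adduct = character(), dmz = numeric(),
                       dccs = numeric(), drt = numeric(), score = numeric(),
                       stringsAsFactors = FALSE)
  }
  n_hits <- table(factor(hits$feature_id, levels = features$feature_id))
  per_feature <- data.frame(feature_id = features$feature_id,
                            n_hits = as.integer(n_hits),
                            stringsAsFactors = FALSE)
  bins <- c(
    "0" = sum(per_feature$n_hits == 0L),
    "1" = sum(per_feature$n_hits == 1L),
    "2-10" = sum(per_feature$n_hits >= 2L & per_feature$n_hits <= 10L),
    ">10" = sum(per_feature$n_hits > 10L)
  )
  structure(list(
    hits = hits,
    per_feature = per_feature,
    n_features = nrow(features),
    n_features_with_hits = sum(per_feature$n_hits > 0L),
    total_hits = nrow(hits),
    bins = bins,
    strategy = strategy
  ), class = "annotation_report")
}

#' @export
print.annotation_report <- function(x, ...) {
  cat(sprintf("Annotation report: %d features, %d with >= 1 hit, %d total hits\n",
              x$n_features, x$n_features_with_hits, x$total_hits))
  cat("  hit-count bins: ",
      paste(names(x$bins), x$bins, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# round half up to integer percent: 46/51 -> 90
.pct <- function(num, den) {
  if (den == 0) return(NA_real_)
  floor(100 * num / den + 0.5)
}

#' Compare two annotation reports
#'
#' Quantifies the filtering effect of the stricter strategy: percentage of
#' features with at least one hit under each, percentage of total hits
#' filtered out, and the shift of the single-hit and >10-hit bins.
#' Percentages are rounded half-up to integer percent; raw fractions are
#' also returned.
#'
#' @param report_1 Report under the weaker strategy (e.g. m/z only).
#' @param report_2 Report under the stricter strategy, over the same
#'   feature set.
#' @return List: \code{pct_features_with_hits_1},
#'   \code{pct_features_with_hits_2}, \code{pct_hits_filtered},
#'   \code{delta_single_hit_pct}, \code{delta_gt10_pct}, plus raw
#'   fractions.
#' @export
hit_statistics <- function(report_1, report_2) {
  if (!setequal(report_1$per_feature$feature_id,
                report_2$per_feature$feature_id)) {
    stop("comparison error: reports cover different feature sets")
  }
  n <- report_1$n_features
  out <- list(
    pct_features_with_hits_1 = .pct(report_1$n_features_with_hits, n),
    pct_features_with_hits_2 = .pct(report_2$n_features_with_hits, n),
    pct_hits_filtered = if (report_1$total_hits > 0)
      100 * (report_1$total_hits - report_2$total_hits) /
        report_1$total_hits else 0,
    delta_single_hit_pct = .pct(report_2$bins[["1"]], n) -
      .pct(report_1$bins[["1"]], n),
    delta_gt10_pct = .pct(report_2$bins[[">10"]], n) -
      .pct(report_1$bins[[">10"]], n),
    frac_features_with_hits_1 = report_1$n_features_with_hits / n,
    frac_features_with_hits_2 = report_2$n_features_with_hits / n,
    total_hits_1 = report_1$total_hits,
    total_hits_2 = report_2$total_hits
  )
  out
}

#' Rank the candidate hits of one feature
#'
#' Score is the mean of normalized errors over the enabled dimensions
#' (|dmz|/mz_tol, |dccs|/ccs_tol, |drt|/rt_tol), ascending; ties are broken
#' lexicographically by (|dmz|, |dccs|, |drt|, metabolite id, adduct) so the
#' order is fully deterministic.
#'
#' @param hits Hit data.frame from \code{\link{match_feature}} (one
#'   feature).
#' @return The hits, sorted, with a \code{rank} column.
#' @export
rank_candidates <- function(hits) {
  if (nrow(hits) == 0L) {
    hits$rank <- integer(0)
    return(hits)
  }
  na0 <- function(v) ifelse(is.na(v), 0, abs(v))
  ord <- order(hits$score, na0(hits$dmz), na0(hits$dccs), na0(hits$drt),
               hits$metabolite_id, hits$adduct)
  out <- hits[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Collapse per-adduct hits to a per-metabolite view
#'
#' A feature may hit several adducts of one metabolite; the collapsed view
#' keeps, per (feature, metabolite), the best-scoring adduct row.
#'
#' @param hits Hit data.frame with a \code{feature_id} column.
#' @return Collapsed data.frame, one row per (feature, metabolite).
#' @export
collapse_hits_by_metabolite <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  key <- paste(hits$feature_id, hits$metabolite_id)
  best <- tapply(seq_len(nrow(hits)), key, function(ix) {
    ix[order(hits$score[ix], abs(hits$dmz[ix]))[1L]]
  })
  out <- hits[sort(unname(best)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
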