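# Schema-validated table readers/writers. CSV dialect: UTF-8, comma, "."
# decimal, mandatory header; TSV accepted by file extension. Units are
# fixed in the column names (rt_min, ccs_A2, mz).

.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "")
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("schema error in ", what, ": missing column(s): ",
         paste(missing, collapse = ", "))
  }
}

.split_rejects <- function(df, bad, reason) {
  rejects <- if (any(bad)) {
    data.frame(row = which(bad), reason = reason, stringsAsFactors = FALSE)
  } else {
    data.frame(row = integer(), reason = character())
  }
  list(data = df[!bad, , drop = FALSE], rejects = rejects)
}

#' Read a standards table
#'
#' Expected columns: \code{id}, \code{name}, \code{formula}, \code{smiles},
#' \code{rt_min}. Row-level problems (negative or missing Rt, empty
#' structures) become reject records rather than silent drops.
#'
#' @param path CSV/TSV path.
#' @return List: \code{data} (valid rows), \code{rejects} (row, reason).
#' @export
read_standards <- function(path) {
  df <- .read_table(path)
  .require_columns(df, c("id", "name", "formula", "smiles", "rt_min"),
                   "standards table")
  df$rt_min <- suppressWarnings(as.numeric(df$rt_min))
  bad <- !is.finite(df$rt_min) | df$rt_min < 0 | !nzchar(df$smiles) |
    is.na(df$smiles)
  out <- .split_rejects(df, bad, "invalid rt_min or empty smiles")
  rownames(out$data) <- NULL
  out
}

#' Read a candidate metabolite table
#'
#' Expected columns: \code{id}, \code{name}, \code{formula},
#' \code{smiles}.
#'
#' @param path CSV/TSV path.
#' @return List: \code{data}, \code{rejects}.
#' @export
read_candidates <- function(path) {
  df <- .read_table(path)
  .require_columns(df, c("id", "name", "formula", "smiles"),
                   "candidate table")
  bad <- is.na(df$smiles) | !nzchar(df$smiles) | is.na(df$id) |
    !nzchar(as.character(df$id))
  out <- .split_rejects(df, bad, "empty id or smiles")
  rownames(out$data) <- NULL
  out
}

#' Read an untargeted feature table
#'
#' Expected columns: \code{feature_id}, \code{mz}, \code{polarity},
#' \code{rt_min}; optional \code{ccs_A2} and \code{intensity}.
#'
#' @param path CSV/TSV path.
#' @return List: \code{data}, \code{rejects}.
#' @export
read_features <- function(path) {
  df <- .read_table(path)
  .require_columns(df, c("feature_id", "mz", "polarity", "rt_min"),
                   "feature table")
  df$mz <- suppressWarnings(as.numeric(df$mz))
  df$rt_min <- suppressWarnings(as.numeric(df$rt_min))
  if ("ccs_A2" %in% names(df)) {
    df$ccs_A2 <- suppressWarnings(as.numeric(df$ccs_A2))
  }
  bad <- !is.finite(df$mz) | df$mz <= 0 | !is.finite(df$rt_min) |
    df$rt_min < 0 | !df$polarity %in% c("positive", "negative")
  out <- .split_rejects(df, bad, "invalid mz, rt_min or polarity")
  rownames(out$data) <- NULL
  out
}

#' Write an annotation report to CSV + JSON
#'
#' Per-feature hits go to \code{<stem>_hits.csv}; the aggregate statistics
#' (feature counts, hit-count bins, strategy) to \code{<stem>_summary.json}.
#'
#' @param report An \code{annotation_report}.
#' @param stem Output path stem.
#' @return Invisibly, the two paths written.
#' @export
write_annotation_report <- function(report, stem) {
  hits_path <- paste0(stem, "_hits.csv")
  json_path <- paste0(stem, "_summary.json")
  utils::write.csv(report$hits, hits_path, row.names = FALSE)
  jsonlite::write_json(list(
    n_features = report$n_features,
    n_features_with_hits = report$n_features_with_hits,
    total_hits = report$total_hits,
    bins = as.list(report$bins),
    strategy = unclass(report$strategy)
  ), json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(hits_path, json_path))
}
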