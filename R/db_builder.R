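# Assembly of the predicted (metabolite, adduct) annotation database and
# its merge with measured standards entries.

.db_columns <- c("metabolite_id", "name", "formula", "adduct", "polarity",
                 "mz", "ccs_A2", "rt_min", "ccs_flag", "rt_flag", "source")

.empty_db <- function() {
  data.frame(metabolite_id = character(), name = character(),
             formula = character(), adduct = character(),
             polarity = character(), mz = numeric(), ccs_A2 = numeric(),
             rt_min = numeric(), ccs_flag = logical(), rt_flag = logical(),
             source = character(), stringsAsFactors = FALSE)
}

#' Build the predicted annotation database
#'
#' For each candidate metabolite: derives the neutral monoisotopic mass
#' from the structure, predicts one retention time (identical across all
#' adduct rows of that metabolite) and a per-adduct m/z and CCS. Failed
#' structures become reject records, never silent drops. Rt predictions
#' outside the chromatographic window are clipped to the boundary and
#' flagged.
#'
#' @param candidates data.frame with columns \code{id}, \code{name},
#'   \code{formula} (may be NA; derived from the structure), \code{smiles}.
#' @param ccs_model A \code{ccs_model}.
#' @param rt_model An \code{rt_model}.
#' @param adducts Adduct labels to generate (default: the model-supported
#'   subset of the full adduct table).
#' @param polarity Restrict to these polarities.
#' @param chunk_size Candidates per processing chunk (bounded memory).
#' @return List: \code{entries} (the database data.frame, columns
#'   \code{metabolite_id}, \code{name}, \code{formula}, \code{adduct},
#'   \code{polarity}, \code{mz}, \code{ccs_A2}, \code{rt_min},
#'   \code{ccs_flag}, \code{rt_flag}, \code{source}) and \code{rejects}
#'   (id, reason).
#' @export
build_database <- function(candidates, ccs_model, rt_model,
                           adducts = ccs_model$adduct_levels,
                           polarity = c("positive", "negative"),
                           chunk_size = 1000L) {
  stopifnot(all(c("id", "smiles") %in% names(candidates)))
  if (!"name" %in% names(candidates)) candidates$name <- candidates$id
  tab <- adduct_table()
  adducts <- normalize_adduct(adducts)
  adducts <- adducts[tab$polarity[match(adducts, tab$label)] %in% polarity]
  if (length(adducts) == 0L) stop("no applicable adducts for polarity ",
                                  paste(polarity, collapse = "/"))
  chunks <- split(seq_len(nrow(candidates)),
                  ceiling(seq_len(nrow(candidates)) / chunk_size))
  entries <- list(); rejects <- list()
  for (ch in chunks) {
    sub <- candidates[ch, , drop = FALSE]
    d <- compute_descriptors(sub$smiles)
    formulas <- attr(d, "formula")
    usable <- attr(d, "parsed") & !is.na(formulas)
    rt <- predict_rt(rt_model, descriptors = d)
    need <- unique(c(rt_model$selected, ccs_model$selected))
    complete <- usable & rowSums(is.na(d[, need, drop = FALSE])) == 0L
    if (any(!usable)) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        id = sub$id[!usable], reason = "unparseable structure")
    }
    if (any(usable & !complete)) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        id = sub$id[usable & !complete], reason = "incomputable descriptors")
    }
    if (!any(complete)) next
    idx <- which(complete)
    mass <- vapply(formulas[idx], monoisotopic_mass, numeric(1L))
    rt_pred <- rt$rt_pred[idx]
    rt_flag <- rt$extrapolation_flag[idx] | rt_pred < 0 |
      rt_pred > rt_model$run_length
    rt_clip <- pmin(pmax(rt_pred, 0), rt_model$run_length)
    grid <- expand.grid(k = seq_along(idx), adduct = adducts,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mz <- adduct_mz(mass[grid$k], grid$adduct)
    p <- predict_ccs_features(ccs_model, d[idx[grid$k], , drop = FALSE],
                              mz, grid$adduct)
    entries[[length(entries) + 1L]] <- data.frame(
      metabolite_id = sub$id[idx[grid$k]],
      name = sub$name[idx[grid$k]],
      formula = formulas[idx[grid$k]],
      adduct = grid$adduct,
      polarity = tab$polarity[match(grid$adduct, tab$label)],
      mz = mz,
      ccs_A2 = p$ccs_pred,
      rt_min = rt_clip[grid$k],
      ccs_flag = p$extrapolation_flag,
      rt_flag = rt_flag[grid$k],
      source = "predicted",
      stringsAsFactors = FALSE)
  }
  entries <- if (length(entries)) do.call(rbind, entries) else .empty_db()
  entries <- entries[order(entries$metabolite_id, entries$adduct), ]
  rownames(entries) <- NULL
  list(entries = entries,
       rejects = if (length(rejects)) do.call(rbind, rejects) else
         data.frame(id = character(), reason = character()))
}

#' Merge measured standards entries into a predicted database
#'
#' Measured rows replace predicted rows on the key
#' (\code{metabolite_id}, \code{adduct}) and carry \code{source =
#' "measured"}; in-house measured values take precedence over predictions.
#' The operation is idempotent.
#'
#' @param db Database data.frame (see \code{\link{build_database}}).
#' @param measured data.frame with columns \code{metabolite_id},
#'   \code{adduct}, \code{mz}, \code{ccs_A2}, \code{rt_min} (and optionally
#'   \code{name}, \code{formula}, \code{polarity}).
#' @return Merged database data.frame.
#' @export
merge_measured <- function(db, measured) {
  if (nrow(measured) == 0L) return(db)
  stopifnot(all(c("metabolite_id", "adduct", "mz", "ccs_A2", "rt_min")
                %in% names(measured)))
  measured$adduct <- normalize_adduct(measured$adduct)
  key <- paste(measured$metabolite_id, measured$adduct)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    agree <- vapply(dup, function(k) {
      rows <- measured[key == k, c("mz", "ccs_A2", "rt_min")]
      all(vapply(rows, function(v) length(unique(v)) == 1L, logical(1L)))
    }, logical(1L))
    if (any(!agree)) {
      stop("merge error: conflicting duplicate measured keys: ",
           paste(dup[!agree], collapse = "; "))
    }
    measured <- measured[!duplicated(key), , drop = FALSE]
    key <- key[!duplicated(key)]
  }
  tab <- adduct_table()
  fill <- function(col, default) {
    if (col %in% names(measured)) measured[[col]] else default
  }
  measured_rows <- data.frame(
    metabolite_id = measured$metabolite_id,
    name = fill("name", measured$metabolite_id),
    formula = fill("formula", NA_character_),
    adduct = measured$adduct,
    polarity = fill("polarity", tab$polarity[match(measured$adduct, tab$label)]),
    mz = measured$mz,
    ccs_A2 = measured$ccs_A2,
    rt_min = measured$rt_min,
    ccs_flag = FALSE,
    rt_flag = FALSE,
    source = "measured",
    stringsAsFactors = FALSE)
  db_key <- paste(db$metabolite_id, db$adduct)
  out <- rbind(db[!db_key %in% key, , drop = FALSE], measured_rows)
  out <- out[order(out$metabolite_id, out$adduct), ]
  rownames(out) <- NULL
  out
}

#' Write / read the annotation database CSV
#'
#' Fixed column order and fixed decimal formatting (m/z to 4 decimals, CCS
#' and Rt to 4), so that write -> read -> write round-trips byte-exactly.
#'
#' @param db Database data.frame.
#' @param path Output CSV path.
#' @return \code{write_database}: the path, invisibly;
#'   \code{read_database}: the database data.frame.
#' @export
write_database <- function(db, path) {
  out <- db[, .db_columns]
  for (col in c("mz", "ccs_A2", "rt_min")) {
    out[[col]] <- sprintf("%.4f", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_database
#' @export
read_database <- function(path) {
  db <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(mz = "numeric", ccs_A2 = "numeric",
                                       rt_min = "numeric",
                                       ccs_flag = "logical",
                                       rt_flag = "logical"))
  db[, .db_columns]
}
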