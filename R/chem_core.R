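# Structure handling, monoisotopic mass and adduct m/z arithmetic, and the
# molecular descriptor panel shared by the Rt and CCS models.

#' Monoisotopic masses of the most abundant isotope of each supported element
#'
#' @format Named numeric vector, Da, >= 6 decimal places (AME2020 values).
#' @keywords internal
.isotope_mass <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.9737616320,
  S  = 31.9720710015,
  Na = 22.9897692809,
  K  = 38.9637064864,
  Cl = 34.9688526800,
  F  = 18.9984032200,
  Br = 78.9183371000,
  I  = 126.904473000,
  Si = 27.9769265325,
  Se = 79.9165218000,
  B  = 11.0093054000,
  Li = 7.0160034366,
  Mg = 23.9850416970,
  Ca = 39.9625908630,
  Fe = 55.9349350000,
  Zn = 63.9291420000,
  Cu = 62.9295970000,
  Mn = 54.9380430000,
  Co = 58.9331940000,
  As = 74.9215950000
)

#' Electron rest mass in Da
#' @keywords internal
.electron_mass <- 0.000548579909

#' Parse a Hill-notation elemental formula
#'
#' Accepts plain element/count formulas such as \code{"C6H12O6"}. Charges,
#' isotope labels, parentheses and dots are rejected rather than guessed.
#'
#' @param formula Character scalar, Hill-notation elemental formula.
#' @return Named integer vector of element counts (all counts >= 1).
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("formula error: formula must be a non-empty character scalar")
  }
  if (grepl("[][()+.^{}'*/\\\\ 0-9-]", substr(formula, 1L, 1L)) ||
      grepl("[][()+.{}'*/\\\\ -]", formula)) {
    stop("formula error: charges, isotopes and groupings are not supported: ",
         formula)
  }
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1L]]
  matched <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula,
                                          perl = TRUE))[[1L]]
  if (sum(nchar(matched)) != nchar(formula)) {
    stop("formula error: unparseable formula: ", formula)
  }
  elements <- sub("[0-9]*$", "", matched)
  counts <- as.integer(ifelse(grepl("[0-9]+$", matched),
                              sub("^[A-Za-z]+", "", matched), "1"))
  unknown <- setdiff(elements, names(.isotope_mass))
  if (length(unknown) > 0L) {
    stop("formula error: unknown element symbol(s): ",
         paste(unknown, collapse = ", "))
  }
  if (any(counts < 1L)) {
    stop("formula error: element count < 1 in: ", formula)
  }
  out <- tapply(counts, elements, sum)
  storage.mode(out) <- "integer"
  out[order(names(out))]
}

#' Monoisotopic mass of an elemental formula
#'
#' Sums, over elements, the mass of the most abundant isotope times the
#' element count. Masses are monoisotopic, never average.
#'
#' @param formula Hill-notation elemental formula string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")     # 18.010565
#' monoisotopic_mass("C6H12O6") # 180.063388
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(.isotope_mass[names(counts)] * counts)
}

# Composition (formula of the attached group) for each supported adduct.
# Mass shifts are derived from the isotope-mass table plus the electron-mass
# charge correction, never typed in as opaque constants.
.adduct_defs <- list(
  "[M+H]+"      = list(gain = "H",      loss = NULL, polarity = "positive"),
  "[M+Na]+"     = list(gain = "Na",     loss = NULL, polarity = "positive"),
  "[M+K]+"      = list(gain = "K",      loss = NULL, polarity = "positive"),
  "[M+NH4]+"    = list(gain = "NH4",    loss = NULL, polarity = "positive"),
  "[M]+"        = list(gain = NULL,     loss = NULL, polarity = "positive"),
  "[M-H]-"      = list(gain = NULL,     loss = "H",  polarity = "negative"),
  "[M+Na-2H]-"  = list(gain = "Na",     loss = "H2", polarity = "negative"),
  "[M+Cl]-"     = list(gain = "Cl",     loss = NULL, polarity = "negative"),
  "[M+HCOO]-"   = list(gain = "CHO2",   loss = NULL, polarity = "negative"),
  "[M+CH3COO]-" = list(gain = "C2H3O2", loss = NULL, polarity = "negative"),
  "[M]-"        = list(gain = NULL,     loss = NULL, polarity = "negative")
)

# Vendor-notation aliases mapped onto canonical labels.  "[M+CH3OO]-" is the
# acetate adduct as printed by some vendor software.
.adduct_aliases <- c(
  "[M+CH3OO]-"  = "[M+CH3COO]-",
  "[M+HCOOH-H]-" = "[M+HCOO]-",
  "[M+FA-H]-"   = "[M+HCOO]-"
)

#' Normalise an adduct label
#'
#' Maps unicode minus signs and known vendor aliases onto the canonical
#' label set.
#' @param label Adduct label string(s).
#' @return Canonical label string(s).
#' @export
normalize_adduct <- function(label) {
  label <- gsub("−", "-", label)
  idx <- match(label, names(.adduct_aliases))
  label[!is.na(idx)] <- .adduct_aliases[idx[!is.na(idx)]]
  label
}

#' Supported adduct table
#'
#' One row per supported ionization adduct with its polarity, charge
#' magnitude and signed mass shift in Da. Mass shifts carry the
#' electron-mass charge correction (e.g. \code{[M+H]+} is +1.007276 Da, not
#' the hydrogen atom mass).
#'
#' @return data.frame with columns \code{label}, \code{polarity},
#'   \code{charge}, \code{mass_shift}.
#' @examples
#' adduct_table()
#' @export
adduct_table <- function() {
  labels <- names(.adduct_defs)
  shift <- vapply(.adduct_defs, function(d) {
    m <- 0
    if (!is.null(d$gain)) m <- m + monoisotopic_mass(d$gain)
    if (!is.null(d$loss)) m <- m - monoisotopic_mass(d$loss)
    if (d$polarity == "positive") m - .electron_mass else m + .electron_mass
  }, numeric(1L))
  data.frame(
    label = labels,
    polarity = vapply(.adduct_defs, `[[`, character(1L), "polarity"),
    charge = 1L,
    mass_shift = unname(shift),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' m/z of an adduct ion
#'
#' Computes \code{(neutral_mass + mass_shift) / charge} for a supported
#' singly-charged adduct. The mass shift includes the electron-mass
#' correction, so e.g. the protonated leucine enkephalin (C28H37N5O7) lock
#' mass evaluates to m/z 556.2766.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0).
#' @param adduct Adduct label (see \code{\link{adduct_table}}); vendor
#'   aliases are accepted.
#' @return m/z in Th, one value per input pair (inputs are recycled).
#' @examples
#' adduct_mz(monoisotopic_mass("C28H37N5O7"), "[M+H]+")
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (any(!is.finite(neutral_mass)) || any(neutral_mass <= 0)) {
    stop("neutral_mass must be finite and > 0")
  }
  tab <- adduct_table()
  adduct <- normalize_adduct(adduct)
  idx <- match(adduct, tab$label)
  if (anyNA(idx)) {
    stop("adduct error: unsupported adduct label(s): ",
         paste(unique(adduct[is.na(idx)]), collapse = ", "))
  }
  (neutral_mass + tab$mass_shift[idx]) / tab$charge[idx]
}

# ---------------------------------------------------------------------------
# SMILES parsing and the descriptor panel
# ---------------------------------------------------------------------------

# smiles2sdf aborts a whole batch when one string is invalid, so structures
# are parsed one at a time and failures flagged rather than silently dropped.
.parse_smiles_one <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    return(NULL)
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) != 1L) return(NULL)
  natoms <- tryCatch(nrow(ChemmineR::atomblock(sdf[[1L]])),
                     error = function(e) 0L)
  if (is.null(natoms) || natoms < 1L) return(NULL)
  sdf
}

#' Names of the molecular descriptor panel
#'
#' The configured 2D descriptor panel: constitutional counts from the
#' elemental formula, OpenBabel physicochemical estimates (logP, TPSA,
#' H-bond donors/acceptors, molar refractivity), ring and functional-group
#' counts, and topological indices (Wiener, Zagreb, Randic, eccentricity
#' statistics) computed on the heavy-atom graph. Panel membership is
#' configuration and is stored inside every trained model artifact.
#'
#' @return Character vector of descriptor names.
#' @export
descriptor_panel <- function() {
  c(
    # physicochemical estimates (OpenBabel)
    "logP", "TPSA", "HBD", "HBA1", "HBA2", "MR", "MW_avg",
    # constitutional (formula-derived)
    "mass_mono", "n_C", "n_H", "n_N", "n_O", "n_P", "n_S", "n_halogen",
    "n_heavy", "n_atoms", "ratio_HC", "ratio_OC", "ratio_NC", "frac_hetero",
    # rings and functional groups (structure-derived)
    "n_rings", "n_aromatic_rings",
    "fg_RNH2", "fg_R2NH", "fg_R3N", "fg_ROPO3", "fg_ROH", "fg_RCHO",
    "fg_RCOR", "fg_RCOOH", "fg_RCOOR", "fg_ROR", "fg_RCCH", "fg_RCN",
    # topological (heavy-atom graph)
    "n_edges", "mean_degree", "n_branch", "n_terminal",
    "zagreb1", "zagreb2", "randic", "wiener",
    "diameter", "radius", "mean_eccentricity", "petitjean"
  )
}

# Topological indices on the heavy-atom connectivity matrix. Returns NA for
# indices undefined on the graph (no edges, or disconnected components with
# infinite distances) -- these propagate into the missing mask.
.topo_descriptors <- function(con) {
  out <- c(n_edges = NA_real_, mean_degree = NA_real_, n_branch = NA_real_,
           n_terminal = NA_real_, zagreb1 = NA_real_, zagreb2 = NA_real_,
           randic = NA_real_, wiener = NA_real_, diameter = NA_real_,
           radius = NA_real_, mean_eccentricity = NA_real_,
           petitjean = NA_real_)
  if (is.null(con) || !is.matrix(con) || nrow(con) < 2L) return(out)
  adj <- (con > 0) * 1
  deg <- rowSums(adj)
  n_edges <- sum(adj) / 2
  if (n_edges < 1) return(out)
  out["n_edges"] <- n_edges
  out["mean_degree"] <- mean(deg)
  out["n_branch"] <- sum(deg >= 3)
  out["n_terminal"] <- sum(deg == 1)
  out["zagreb1"] <- sum(deg^2)
  ij <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  out["zagreb2"] <- sum(deg[ij[, 1L]] * deg[ij[, 2L]])
  out["randic"] <- sum(1 / sqrt(deg[ij[, 1L]] * deg[ij[, 2L]]))
  # BFS all-pairs shortest paths on an unweighted graph
  n <- nrow(adj)
  nb <- apply(adj > 0, 1L, which, simplify = FALSE)
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    frontier <- s
    lev <- 0
    while (length(frontier) > 0L) {
      lev <- lev + 1
      nxt <- unique(unlist(nb[frontier], use.names = FALSE))
      nxt <- nxt[!is.finite(d[nxt])]
      d[nxt] <- lev
      frontier <- nxt
    }
    dist[s, ] <- d
  }
  if (any(!is.finite(dist))) return(out)  # disconnected (e.g. salts)
  out["wiener"] <- sum(dist[upper.tri(dist)])
  ecc <- apply(dist, 1L, max)
  out["diameter"] <- max(ecc)
  out["radius"] <- min(ecc)
  out["mean_eccentricity"] <- mean(ecc)
  out["petitjean"] <- if (min(ecc) > 0) (max(ecc) - min(ecc)) / min(ecc) else NA_real_
  out
}

.descriptors_one <- function(smiles) {
  panel <- descriptor_panel()
  vals <- stats::setNames(rep(NA_real_, length(panel)), panel)
  sdf <- .parse_smiles_one(smiles)
  if (is.null(sdf)) {
    attr(vals, "parsed") <- FALSE
    attr(vals, "formula") <- NA_character_
    return(vals)
  }
  ChemmineR::cid(sdf) <- "m1"
  prop <- tryCatch(suppressWarnings(ChemmineR::propOB(sdf)),
                   error = function(e) NULL)
  formula <- NA_character_
  if (!is.null(prop) && nrow(prop) == 1L) {
    formula <- as.character(prop$formula[1L])
    vals["logP"] <- as.numeric(prop$logP[1L])
    vals["TPSA"] <- as.numeric(prop$TPSA[1L])
    vals["HBD"] <- as.numeric(prop$HBD[1L])
    vals["HBA1"] <- as.numeric(prop$HBA1[1L])
    vals["HBA2"] <- as.numeric(prop$HBA2[1L])
    vals["MR"] <- as.numeric(prop$MR[1L])
    vals["MW_avg"] <- as.numeric(prop$MW[1L])
  }
  if (!is.na(formula) && nzchar(formula)) {
    counts <- tryCatch(parse_formula(formula), error = function(e) NULL)
    if (!is.null(counts)) {
      cnt <- function(el) if (el %in% names(counts)) as.numeric(counts[[el]]) else 0
      vals["mass_mono"] <- sum(.isotope_mass[names(counts)] * counts)
      vals["n_C"] <- cnt("C"); vals["n_H"] <- cnt("H")
      vals["n_N"] <- cnt("N"); vals["n_O"] <- cnt("O")
      vals["n_P"] <- cnt("P"); vals["n_S"] <- cnt("S")
      vals["n_halogen"] <- cnt("F") + cnt("Cl") + cnt("Br") + cnt("I")
      vals["n_atoms"] <- sum(counts)
      vals["n_heavy"] <- sum(counts) - cnt("H")
      if (cnt("C") > 0) {
        vals["ratio_HC"] <- cnt("H") / cnt("C")
        vals["ratio_OC"] <- cnt("O") / cnt("C")
        vals["ratio_NC"] <- cnt("N") / cnt("C")
      }
      if (vals["n_heavy"] > 0) {
        vals["frac_hetero"] <- (vals["n_heavy"] - cnt("C")) / vals["n_heavy"]
      }
    }
  }
  rng <- tryCatch(ChemmineR::rings(sdf[[1L]], type = "count", arom = TRUE),
                  error = function(e) NULL)
  if (!is.null(rng)) {
    vals["n_rings"] <- as.numeric(rng[["RINGS"]])
    vals["n_aromatic_rings"] <- as.numeric(rng[["AROMATIC"]])
  }
  grp <- tryCatch(ChemmineR::groups(sdf, type = "countMA"),
                  error = function(e) NULL)
  if (!is.null(grp)) {
    g <- if (is.matrix(grp)) grp[1L, ] else grp
    for (nm in names(g)) {
      key <- paste0("fg_", nm)
      if (key %in% panel) vals[key] <- as.numeric(g[[nm]])
    }
  }
  con <- tryCatch(ChemmineR::conMA(sdf[[1L]], exclude = "H"),
                  error = function(e) NULL)
  vals[names(.topo_descriptors(con))] <- .topo_descriptors(con)
  attr(vals, "parsed") <- TRUE
  attr(vals, "formula") <- formula
  vals
}

#' Compute the molecular descriptor panel for SMILES structures
#'
#' Deterministically converts each structure into the configured descriptor
#' panel (\code{\link{descriptor_panel}}). Descriptors a structure cannot
#' support (e.g. topological distances on a disconnected salt) are returned
#' as \code{NA} and flagged through the missing mask; unparseable structures
#' are flagged, never silently dropped.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strict If \code{TRUE}, raise a structure error on the first
#'   unparseable string instead of flagging it.
#' @return Numeric matrix (structures x descriptors) with attributes
#'   \code{parsed} (logical vector: structure parsed at all) and
#'   \code{formula} (character vector of derived Hill formulas). \code{NA}
#'   entries are the missing mask.
#' @export
compute_descriptors <- function(smiles, strict = FALSE) {
  panel <- descriptor_panel()
  n <- length(smiles)
  mat <- matrix(NA_real_, n, length(panel),
                dimnames = list(names(smiles) %||% smiles, panel))
  parsed <- logical(n)
  formulas <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    v <- .descriptors_one(smiles[[i]])
    if (!isTRUE(attr(v, "parsed"))) {
      if (strict) stop("structure error: unparseable SMILES: ", smiles[[i]])
      parsed[i] <- FALSE
    } else {
      parsed[i] <- TRUE
      formulas[i] <- attr(v, "formula")
    }
    mat[i, ] <- as.numeric(v)
  }
  attr(mat, "parsed") <- parsed
  attr(mat, "formula") <- formulas
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a
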