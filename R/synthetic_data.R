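# Synthetic standards libraries, candidate databases and untargeted feature
# tables with known ground truth, so the full train -> calibrate -> build ->
# annotate chain is testable without any external download.

# Curated common-metabolite structures (amino acids, sugars, nucleosides,
# organic acids, biogenic amines, vitamins, small lipids), extended by
# homologous series so the pool spans a wide hydrophobicity and mass range.
.curated_smiles <- c(
  glycine = "NCC(=O)O",
  alanine = "CC(N)C(=O)O",
  valine = "CC(C)C(N)C(=O)O",
  leucine = "CC(C)CC(N)C(=O)O",
  isoleucine = "CCC(C)C(N)C(=O)O",
  proline = "OC(=O)C1CCCN1",
  phenylalanine = "NC(Cc1ccccc1)C(=O)O",
  tryptophan = "NC(Cc1c[nH]c2ccccc12)C(=O)O",
  methionine = "CSCCC(N)C(=O)O",
  serine = "NC(CO)C(=O)O",
  threonine = "CC(O)C(N)C(=O)O",
  cysteine = "NC(CS)C(=O)O",
  tyrosine = "NC(Cc1ccc(O)cc1)C(=O)O",
  asparagine = "NC(=O)CC(N)C(=O)O",
  glutamine = "NC(=O)CCC(N)C(=O)O",
  aspartate = "OC(=O)CC(N)C(=O)O",
  glutamate = "OC(=O)CCC(N)C(=O)O",
  lysine = "NCCCCC(N)C(=O)O",
  arginine = "NC(=N)NCCCC(N)C(=O)O",
  histidine = "NC(Cc1c[nH]cn1)C(=O)O",
  ornithine = "NCCCC(N)C(=O)O",
  citrulline = "NC(=O)NCCCC(N)C(=O)O",
  sarcosine = "CNCC(=O)O",
  glucose = "OCC1OC(O)C(O)C(O)C1O",
  fructose = "OCC1(O)OCC(O)C(O)C1O",
  ribose = "OCC1OC(O)C(O)C1O",
  sorbitol = "OCC(O)C(O)C(O)C(O)CO",
  myo_inositol = "OC1C(O)C(O)C(O)C(O)C1O",
  glucuronic_acid = "OC(=O)C1OC(O)C(O)C(O)C1O",
  n_acetylglucosamine = "CC(=O)NC1C(O)OC(CO)C(O)C1O",
  sucrose = "OCC1OC(OC2(CO)OC(CO)C(O)C2O)C(O)C(O)C1O",
  glycerol = "OCC(O)CO",
  adenine = "Nc1ncnc2[nH]cnc12",
  guanine = "Nc1nc2[nH]cnc2c(=O)[nH]1",
  cytosine = "Nc1cc[nH]c(=O)n1",
  uracil = "O=c1cc[nH]c(=O)[nH]1",
  thymine = "Cc1c[nH]c(=O)[nH]c1=O",
  hypoxanthine = "O=c1[nH]cnc2[nH]cnc12",
  xanthine = "O=c1[nH]c2[nH]cnc2c(=O)[nH]1",
  adenosine = "OCC1OC(n2cnc3c(N)ncnc32)C(O)C1O",
  uridine = "OCC1OC(n2ccc(=O)[nH]c2=O)C(O)C1O",
  inosine = "OCC1OC(n2cnc3c2ncnc3O)C(O)C1O",
  caffeine = "Cn1c(=O)c2c(ncn2C)n(C)c1=O",
  theobromine = "Cn1cnc2c1c(=O)[nH]c(=O)n2C",
  citric_acid = "OC(=O)CC(O)(CC(=O)O)C(=O)O",
  malic_acid = "OC(CC(=O)O)C(=O)O",
  fumaric_acid = "OC(=O)C=CC(=O)O",
  succinic_acid = "OC(=O)CCC(=O)O",
  lactic_acid = "CC(O)C(=O)O",
  pyruvic_acid = "CC(=O)C(=O)O",
  oxoglutaric_acid = "OC(=O)CCC(=O)C(=O)O",
  tartaric_acid = "OC(C(O)C(=O)O)C(=O)O",
  glycolic_acid = "OCC(=O)O",
  oxalic_acid = "OC(=O)C(=O)O",
  benzoic_acid = "OC(=O)c1ccccc1",
  salicylic_acid = "OC(=O)c1ccccc1O",
  hippuric_acid = "OC(=O)CNC(=O)c1ccccc1",
  vanillic_acid = "COc1cc(C(=O)O)ccc1O",
  ferulic_acid = "COc1cc(C=CC(=O)O)ccc1O",
  caffeic_acid = "Oc1ccc(C=CC(=O)O)cc1O",
  cinnamic_acid = "OC(=O)C=Cc1ccccc1",
  shikimic_acid = "OC1CC(C(=O)O)=CC(O)C1O",
  ethanolamine = "NCCO",
  putrescine = "NCCCCN",
  spermidine = "NCCCCNCCCN",
  histamine = "NCCc1c[nH]cn1",
  serotonin = "NCCc1c[nH]c2ccc(O)cc12",
  dopamine = "NCCc1ccc(O)c(O)c1",
  tyramine = "NCCc1ccc(O)cc1",
  tryptamine = "NCCc1c[nH]c2ccccc12",
  epinephrine = "CNCC(O)c1ccc(O)c(O)c1",
  melatonin = "CC(=O)NCCc1c[nH]c2ccc(OC)cc12",
  niacin = "OC(=O)c1cccnc1",
  nicotinamide = "NC(=O)c1cccnc1",
  pyridoxine = "Cc1ncc(CO)c(CO)c1O",
  pantothenic_acid = "CC(C)(CO)C(O)C(=O)NCCC(=O)O",
  biotin = "OC(=O)CCCCC1SCC2NC(=O)NC12",
  ascorbic_acid = "OC1=C(O)C(=O)OC1C(O)CO",
  creatinine = "CN1CC(=O)N=C1N",
  creatine = "CN(CC(=O)O)C(=N)N",
  urea = "NC(=O)N",
  taurine = "NCCS(=O)(=O)O",
  glutathione = "NC(CCC(=O)NC(CS)C(=O)NCC(=O)O)C(=O)O",
  uric_acid = "O=c1[nH]c(=O)c2[nH]c(=O)[nH]c2[nH]1",
  indole_3_acetic_acid = "OC(=O)Cc1c[nH]c2ccccc12",
  kynurenine = "NC(Cc1ccccc1N)C(=O)O",
  anthranilic_acid = "Nc1ccccc1C(=O)O",
  phenylacetic_acid = "OC(=O)Cc1ccccc1",
  p_cresol = "Cc1ccc(O)cc1",
  cholesterol = "CC(C)CCCC(C)C1CCC2C1(C)CCC1C2CC=C2CC(O)CCC21C",
  testosterone = "CC12CCC3C(CCC4=CC(=O)CCC43C)C1CCC2O",
  cortisol = "CC12CC(O)C3C(CCC4=CC(=O)CCC43C)C1CCC2(O)C(=O)CO",
  oleic_acid = "CCCCCCCCC=CCCCCCCCC(=O)O",
  linoleic_acid = "CCCCCC=CCC=CCCCCCCCC(=O)O",
  arachidonic_acid = "CCCCCC=CCC=CCC=CCC=CCCCC(=O)O",
  palmitoleic_acid = "CCCCCCC=CCCCCCCCC(=O)O"
)

.homologous_series <- function() {
  chain <- function(k) strrep("C", k)
  series <- c(
    # fatty acids C3..C22
    stats::setNames(paste0(chain(2:21), "C(=O)O"),
                    paste0("fatty_acid_C", 3:22)),
    # alpha,omega-dicarboxylic acids
    stats::setNames(paste0("OC(=O)", chain(1:10), "C(=O)O"),
                    paste0("diacid_C", 3:12)),
    # 1-alkanols
    stats::setNames(paste0(chain(3:14), "O"), paste0("alkanol_C", 3:14)),
    # 1-alkylamines
    stats::setNames(paste0(chain(4:12), "N"), paste0("alkylamine_C", 4:12)),
    # N-acylglycines
    stats::setNames(paste0(chain(2:11), "C(=O)NCC(=O)O"),
                    paste0("acylglycine_C", 3:12)),
    # 2-hydroxy acids
    stats::setNames(paste0(chain(2:10), "C(O)C(=O)O"),
                    paste0("hydroxyacid_C", 4:12)),
    # methyl ketones
    stats::setNames(paste0(chain(3:11), "C(C)=O"),
                    paste0("ketone_C", 5:13)),
    # alkylbenzenes
    stats::setNames(paste0(chain(2:9), "c1ccccc1"),
                    paste0("alkylbenzene_C", 2:9)),
    # 4-alkylphenols
    stats::setNames(paste0("Oc1ccc(", chain(2:9), ")cc1"),
                    paste0("alkylphenol_C", 2:9)),
    # N-acylethanolamines
    stats::setNames(paste0(chain(3:12), "C(=O)NCCO"),
                    paste0("acylethanolamine_C", 4:13)),
    # alkyl glucosides
    stats::setNames(paste0(chain(1:8), "OC1OC(CO)C(O)C(O)C1O"),
                    paste0("alkylglucoside_C", 1:8)),
    # omega-amino acids (beta-alanine, GABA, ...)
    stats::setNames(paste0("N", chain(2:9), "C(=O)O"),
                    paste0("aminoacid_omega_C", 3:10)),
    # fatty acid methyl esters
    stats::setNames(paste0(chain(3:12), "C(=O)OC"),
                    paste0("methylester_C", 5:14)),
    # alkane-1,n-diols
    stats::setNames(paste0("O", chain(2:10), "O"), paste0("diol_C", 2:10)),
    # fatty amides
    stats::setNames(paste0(chain(3:11), "C(N)=O"),
                    paste0("fattyamide_C", 4:12)),
    # phenylalkanoic acids
    stats::setNames(paste0("OC(=O)", chain(2:7), "c1ccccc1"),
                    paste0("phenylacid_C", 2:7)),
    # indolealkanoic acids
    stats::setNames(paste0("OC(=O)", chain(2:5), "c1c[nH]c2ccccc12"),
                    paste0("indoleacid_C", 2:5)),
    # alkylpyridines
    stats::setNames(paste0(chain(2:6), "c1ccncc1"),
                    paste0("alkylpyridine_C", 2:6)),
    # 1-monoacylglycerols
    stats::setNames(paste0(chain(3:12), "C(=O)OCC(O)CO"),
                    paste0("monoacylglycerol_C", 4:13)),
    # N-acetyl alkylamines
    stats::setNames(paste0("CC(=O)N", chain(2:8)),
                    paste0("acetamide_C", 4:10)),
    # omega-hydroxy acids
    stats::setNames(paste0("OC", chain(2:10), "C(=O)O"),
                    paste0("omegahydroxyacid_C", 4:12)),
    # 2-alkenoic acids
    stats::setNames(paste0(chain(2:10), "C=CC(=O)O"),
                    paste0("alkenoicacid_C", 5:13)),
    # alkyl acetates
    stats::setNames(paste0("CC(=O)O", chain(2:9)),
                    paste0("alkylacetate_C", 4:11))
  )
  series
}

#' The bundled metabolite structure pool
#'
#' Hand-curated common-metabolite SMILES (amino acids, sugars, nucleosides,
#' organic acids, biogenic amines, vitamins, small lipids) extended with
#' homologous-series templates. All structures are valid, chemically
#' meaningful, and span roughly 60-600 Da.
#'
#' @return data.frame with columns \code{name}, \code{smiles} (>= 300
#'   rows, unique structures).
#' @export
metabolite_pool <- function() {
  all <- c(.curated_smiles, .homologous_series())
  all <- all[!duplicated(unname(all))]
  data.frame(name = names(all), smiles = unname(all),
             stringsAsFactors = FALSE)
}

# Cached pool descriptors: the pool is fixed, so its descriptor matrix is
# computed once per session.
.pool_cache <- new.env(parent = emptyenv())

.pool_descriptors <- function() {
  if (is.null(.pool_cache$desc)) {
    pool <- metabolite_pool()
    d <- compute_descriptors(pool$smiles)
    rownames(d) <- pool$name
    .pool_cache$pool <- pool
    .pool_cache$desc <- d
  }
  list(pool = .pool_cache$pool, desc = .pool_cache$desc)
}

#' Default generator truth constants
#'
#' The study conditions the generator emulates: a 17-min reversed-phase
#' gradient (Rt bounded in [0.7, 17.0] min), a square-root CCS-vs-mass
#' trend with three latent compound classes, per-adduct CCS offsets, and
#' measurement noise at the scale of routine ion-mobility LC-HRMS
#' (Rt noise 0.3 min, CCS noise 2 Å², m/z jitter 1 mDa).
#'
#' @return Named list of generator constants.
#' @export
synthetic_truth_defaults <- function() {
  list(
    rt_L = 0.7, rt_U = 17.0, rt_w = 1.3,
    ccs_A = c(10.8, 12.2, 13.6),   # A^2 / sqrt(Da), per latent class
    ccs_b = 0.5,
    ccs_delta = c("[M+H]+" = 0, "[M+Na]+" = 2.5, "[M+K]+" = 5,
                  "[M+NH4]+" = 1.5, "[M]+" = 0, "[M-H]-" = -2,
                  "[M+Na-2H]-" = 0.5, "[M+Cl]-" = 4, "[M+HCOO]-" = 6.5,
                  "[M+CH3COO]-" = 9, "[M]-" = 0),
    rt_noise = 0.3, ccs_noise = 2, mz_jitter = 0.001
  )
}

.true_ccs <- function(truth, class, neutral_mass, adduct) {
  adduct <- normalize_adduct(adduct)
  shift <- adduct_table()$mass_shift[match(adduct, adduct_table()$label)]
  truth$ccs_A[class] * (neutral_mass + shift)^truth$ccs_b +
    truth$ccs_delta[adduct]
}

#' Generate a synthetic standards library with known ground truth
#'
#' Samples \code{n} structures from the bundled pool, assigns each a latent
#' compound class by chemical family (aromatic, polar, aliphatic -- a
#' deterministic function of the descriptors), and attaches the true
#' retention time (a logistic function of a
#' standardized hydrophobicity-dominated descriptor combination, bounded in
#' [0.7, 17.0] min) and the true per-adduct CCS trend
#' \code{A_class * (mass + shift)^0.5 + delta_adduct}.
#'
#' @param n Number of compounds (> 0, <= pool size).
#' @param seed Integer seed; output is a pure function of (n, seed).
#' @param truth Generator constants (\code{\link{synthetic_truth_defaults}}).
#' @return List: \code{records} (id, name, formula, smiles, neutral_mass,
#'   class, true_rt), \code{descriptors} (matrix, rows aligned), and
#'   \code{truth} (constants used).
#' @export
generate_library <- function(n, seed = 1L, truth = synthetic_truth_defaults()) {
  if (!is.numeric(n) || n <= 0) stop("domain error: n must be > 0")
  pd <- .pool_descriptors()
  usable <- which(attr(pd$desc, "parsed") &
                    rowSums(is.na(pd$desc)) == 0L &
                    !is.na(attr(pd$desc, "formula")))
  if (n > length(usable)) {
    stop("domain error: n exceeds the usable structure pool (",
         length(usable), ")")
  }
  set.seed(seed)
  pick <- sort(sample(usable, n))
  pool <- pd$pool[pick, , drop = FALSE]
  desc <- pd$desc[pick, , drop = FALSE]
  formulas <- attr(pd$desc, "formula")[pick]
  mass <- vapply(formulas, monoisotopic_mass, numeric(1L))

  # latent class = chemical family, a deterministic function of structure:
  # planar aromatics pack more compactly per unit mass than polar
  # (sugar-like) compounds, which in turn sit below extended aliphatics
  class <- ifelse(desc[, "n_aromatic_rings"] >= 1, 1L,
                  ifelse(desc[, "TPSA"] >= 75, 2L, 3L))

  # hydrophobicity-dominated combination drives the true Rt
  z0 <- 0.9 * desc[, "logP"] + 0.02 * desc[, "MR"] - 0.01 * desc[, "TPSA"]
  z <- as.numeric(scale(z0))
  true_rt <- truth$rt_L + (truth$rt_U - truth$rt_L) *
    stats::plogis(truth$rt_w * z)

  records <- data.frame(
    id = sprintf("SYN%04d", seq_len(n)),
    name = pool$name,
    formula = unname(formulas),
    smiles = pool$smiles,
    neutral_mass = unname(mass),
    class = class,
    true_rt = true_rt,
    stringsAsFactors = FALSE)
  rownames(desc) <- records$id
  list(records = records, descriptors = desc, truth = truth)
}

# Adducts measured on the instrument, per polarity.
.measured_adducts <- list(
  positive = c("[M+H]+", "[M+Na]+", "[M+K]+"),
  negative = c("[M-H]-", "[M+Cl]-", "[M+HCOO]-", "[M+CH3COO]-")
)

#' Simulate measured standards from a synthetic library
#'
#' Adds Gaussian measurement noise to the true Rt and CCS, draws detected
#' ionization modes and adducts per compound, and marks a small fraction of
#' compounds descriptor-incomplete so downstream exclusion paths are
#' exercised (the scale mirrors a handful out of ~200).
#'
#' @param library Output of \code{\link{generate_library}}.
#' @param seed Integer seed.
#' @param rt_noise,ccs_noise Measurement noise SDs (min, Å²); the truth
#'   defaults are used when omitted.
#' @param p_mode Detection probability per ionization mode (at least one
#'   mode is forced).
#' @param p_secondary_adduct Inclusion probability of each non-primary
#'   adduct within a detected mode.
#' @param p_descriptor_incomplete Probability a compound is flagged
#'   descriptor-incomplete.
#' @return List: \code{standards} (one row per compound: id, name, formula,
#'   smiles, rt_min, descriptor_incomplete), \code{ccs_entries} (one row
#'   per (compound, adduct): id, smiles, adduct, polarity, mz, ccs_A2), and
#'   \code{truth_rt}, \code{truth_ccs} columns carried alongside for
#'   evaluation.
#' @export
simulate_measurements <- function(library, seed = 1L,
                                  rt_noise = library$truth$rt_noise,
                                  ccs_noise = library$truth$ccs_noise,
                                  p_mode = c(positive = 0.7, negative = 0.75),
                                  p_secondary_adduct = 0.25,
                                  p_descriptor_incomplete = 7 / 204) {
  rec <- library$records
  truth <- library$truth
  n <- nrow(rec)
  set.seed(seed)
  rt_meas <- rec$true_rt + stats::rnorm(n, 0, rt_noise)
  incomplete <- stats::runif(n) < p_descriptor_incomplete
  in_pos <- stats::runif(n) < p_mode[["positive"]]
  in_neg <- stats::runif(n) < p_mode[["negative"]]
  neither <- !in_pos & !in_neg
  in_pos[neither] <- stats::runif(sum(neither)) < 0.5
  in_neg[neither] <- !in_pos[neither]

  entries <- list()
  for (mode in c("positive", "negative")) {
    detected <- if (mode == "positive") in_pos else in_neg
    adducts <- .measured_adducts[[mode]]
    for (i in which(detected)) {
      take <- c(TRUE, stats::runif(length(adducts) - 1L) < p_secondary_adduct)
      for (a in adducts[take]) {
        true_ccs <- .true_ccs(truth, rec$class[i], rec$neutral_mass[i], a)
        entries[[length(entries) + 1L]] <- data.frame(
          id = rec$id[i], smiles = rec$smiles[i], adduct = a,
          polarity = mode,
          mz = adduct_mz(rec$neutral_mass[i], a),
          ccs_A2 = true_ccs + stats::rnorm(1L, 0, ccs_noise),
          true_ccs = true_ccs,
          stringsAsFactors = FALSE)
      }
    }
  }
  ccs_entries <- do.call(rbind, entries)
  rownames(ccs_entries) <- NULL
  list(
    standards = data.frame(
      id = rec$id, name = rec$name, formula = rec$formula,
      smiles = rec$smiles, rt_min = rt_meas, true_rt = rec$true_rt,
      descriptor_incomplete = incomplete, stringsAsFactors = FALSE),
    ccs_entries = ccs_entries
  )
}

#' Simulate an untargeted feature table with planted truth
#'
#' True features are database rows jittered well within the match windows;
#' decoy database rows are planted within the m/z tolerance of a feature
#' but displaced beyond the CCS and/or Rt window by a construction factor
#' (default 1.5 x tolerance), so the m/z-only strategy hits them and the
#' combined strategy excludes them; noise features match nothing within the
#' m/z tolerance.
#'
#' @param db Database data.frame (see \code{\link{build_database}}).
#' @param n_true,n_decoy,n_noise Feature counts by kind.
#' @param seed Integer seed.
#' @param mz_tol,ccs_tol,rt_tol Tolerances the decoy construction is
#'   relative to (the same values should be used for matching).
#' @param mz_jitter,rt_jitter,ccs_jitter Jitter SDs for true features.
#' @param decoy_factor Displacement of decoys, in units of the tolerance.
#' @return List: \code{features}, \code{db} (input plus planted decoy
#'   rows), \code{labels} (feature_id, kind, metabolite_id, adduct).
#' @export
simulate_feature_table <- function(db, n_true, n_decoy, n_noise, seed = 1L,
                                   mz_tol = 0.005, ccs_tol = 16,
                                   rt_tol = 1.1, mz_jitter = 0.001,
                                   rt_jitter = 0.1, ccs_jitter = 1,
                                   decoy_factor = 1.5) {
  stopifnot(nrow(db) > 0L)
  metabolites <- unique(db$metabolite_id)
  if (n_true > length(metabolites)) {
    stop("n_true exceeds the number of distinct database metabolites")
  }
  set.seed(seed)
  feats <- list(); labels <- list()
  fid <- 0L
  new_fid <- function() sprintf("FT%04d", fid)

  true_rows <- integer(0)
  if (n_true > 0L) {
    chosen <- sample(metabolites, n_true)
    true_rows <- vapply(chosen, function(m) {
      rows <- which(db$metabolite_id == m)
      rows[sample.int(length(rows), 1L)]
    }, integer(1L))
    for (r in true_rows) {
      fid <- fid + 1L
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = new_fid(),
        mz = db$mz[r] + stats::rnorm(1L, 0, mz_jitter),
        polarity = db$polarity[r],
        rt_min = db$rt_min[r] + stats::rnorm(1L, 0, rt_jitter),
        ccs_A2 = db$ccs_A2[r] + stats::rnorm(1L, 0, ccs_jitter),
        intensity = stats::rlnorm(1L, 10, 1),
        stringsAsFactors = FALSE)
      labels[[length(labels) + 1L]] <- data.frame(
        feature_id = new_fid(), kind = "true",
        metabolite_id = db$metabolite_id[r], adduct = db$adduct[r],
        stringsAsFactors = FALSE)
    }
  }

  decoy_rows <- list()
  if (n_decoy > 0L) {
    if (n_true == 0L) stop("decoy error: decoys require true features")
    targets <- rep_len(seq_len(n_true), n_decoy)
    for (k in seq_len(n_decoy)) {
      f <- feats[[targets[k]]]
      dim_choice <- sample(c("ccs", "rt", "both"), 1L)
      ccs_off <- if (dim_choice %in% c("ccs", "both")) {
        sample(c(-1, 1), 1L) * decoy_factor * ccs_tol
      } else 0
      rt_off <- if (dim_choice %in% c("rt", "both")) {
        if (f$rt_min - decoy_factor * rt_tol < 0) decoy_factor * rt_tol
        else sample(c(-1, 1), 1L) * decoy_factor * rt_tol
      } else 0
      decoy_rows[[k]] <- data.frame(
        metabolite_id = sprintf("DECOY%04d", k),
        name = sprintf("decoy %d", k),
        formula = NA_character_,
        adduct = if (f$polarity == "positive") "[M+H]+" else "[M-H]-",
        polarity = f$polarity,
        mz = f$mz + stats::runif(1L, -0.8, 0.8) * mz_tol,
        ccs_A2 = f$ccs_A2 + ccs_off,
        rt_min = f$rt_min + rt_off,
        ccs_flag = FALSE, rt_flag = FALSE,
        source = "predicted",
        stringsAsFactors = FALSE)
      labels[[length(labels) + 1L]] <- data.frame(
        feature_id = f$feature_id, kind = "decoy",
        metabolite_id = sprintf("DECOY%04d", k),
        adduct = decoy_rows[[k]]$adduct,
        stringsAsFactors = FALSE)
    }
  }
  db_aug <- rbind(db, do.call(rbind, decoy_rows))

  if (n_noise > 0L) {
    mz_range <- range(db_aug$mz)
    for (k in seq_len(n_noise)) {
      repeat {
        mz <- stats::runif(1L, mz_range[1L], mz_range[2L])
        if (min(abs(db_aug$mz - mz)) > 2 * mz_tol) break
      }
      fid <- fid + 1L
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = new_fid(), mz = mz,
        polarity = sample(c("positive", "negative"), 1L),
        rt_min = stats::runif(1L, 0.7, 17),
        ccs_A2 = stats::runif(1L, 120, 320),
        intensity = stats::rlnorm(1L, 9, 1),
        stringsAsFactors = FALSE)
      labels[[length(labels) + 1L]] <- data.frame(
        feature_id = new_fid(), kind = "noise",
        metabolite_id = NA_character_, adduct = NA_character_,
        stringsAsFactors = FALSE)
    }
  }

  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  labels <- do.call(rbind, labels)
  rownames(labels) <- NULL
  list(features = features, db = db_aug, labels = labels)
}
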