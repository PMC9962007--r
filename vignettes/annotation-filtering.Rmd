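---
title: "Predicted Rt and CCS windows for filtering metabolite annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicted Rt and CCS windows for filtering metabolite annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Untargeted LC–IMS–HRMS metabolomics extracts thousands of features, each a
(m/z, Rt, CCS) triple, and annotates them by matching accurate mass against
candidate databases of 10^5 metabolites. At a realistic mass tolerance
(5 mDa) almost every feature collects many candidate hits, most of them
false. Two orthogonal, structure-predictable properties can prune them:
retention time (Rt), which depends on the chromatographic method, and the
ion's collision cross-section (CCS), which is method-transferable. Neither
is tabulated for most candidates, so both must be predicted from structure,
and — crucially — the prediction error must be quantified so that the match
window excludes false positives without discarding true ones.

`ccsrt` implements that workflow end to end: descriptor computation, a QSRR
(quantitative structure–retention relationship) Rt model, a cluster-based
CCS model, tolerance calibration, database assembly, and tolerance-window
annotation, plus a ground-truth synthetic generator that makes the whole
chain testable.

## Models

### Molecular descriptors

Structures enter as SMILES and are converted (via ChemmineR/OpenBabel) to a
fixed 2D descriptor panel of ~47 values: physicochemical estimates (logP,
TPSA, H-bond donors/acceptors, molar refractivity), constitutional counts
from the Hill formula, ring and functional-group counts, and topological
indices (Wiener, Zagreb, Randić, eccentricity statistics) computed on the
heavy-atom graph. Descriptors a structure cannot support — distance-based
indices on disconnected structures, ratios on carbon-free formulas — are
returned as missing and masked; compounds with missing values in the
retained panel are excluded from training, with their identities recorded.
Panel membership is configuration and is stored inside every model
artifact, because a prediction is only reproducible together with the exact
descriptor set that produced it.

### QSRR retention model

Before fitting, descriptors are filtered in a fixed order: any-missing
columns, near-zero variance (< 1e-8), then one member of every pair with
|r| > 0.95 (the later-indexed column is dropped, making the result
deterministic). Retained descriptors are standardized and a radial-kernel
support-vector regression is fitted; the hyperparameters (cost, kernel
width, epsilon tube) are chosen by seeded internal cross-validation over a
small grid. Accuracy is estimated by k-fold cross-validation (default
k = 10) in which filtering, standardization and the grid search are all
repeated inside each fold, so the held-out metrics carry no leakage; the
suite asserts CV R² can exceed the training R² by at most 0.02. Fold
membership is assigned after sorting rows into a canonical order, so the
metrics do not depend on the order rows arrive in. Predictions carry an
extrapolation flag whenever a scaled descriptor leaves the training range
or the prediction leaves the chromatographic window — large compounds far
from the training chemistry should not be trusted, only flagged.

### Cluster-based CCS model

CCS is modelled per (compound, adduct) entry. The feature vector is the
filtered descriptor block, the ion m/z, its square root (CCS grows roughly
with the square root of ion mass, so the dominant trend is given to the
model explicitly), and a one-hot adduct encoding that also carries
polarity, so both ESI modes are modelled jointly. Entries are standardized
and partitioned by seeded k-means; the cluster count is either fixed or
chosen by mean silhouette width over k = 2..8. One regressor is fitted per
cluster — radial SVR by default, with the response standardized within the
cluster so the epsilon tube is scale-free; a per-cluster least-squares
option exists and, at k = 1, is verified against a closed-form
normal-equations oracle. Clusters that fall under a minimum occupancy
(default 15 entries) trigger an automatic reduction of k, down to a single
global regressor. At prediction time an entry is routed to its nearest
cluster center and flagged when its distance exceeds the largest training
distance of that cluster.

### Calibration and tolerance windows

Predicted values are compared to measured ones by ordinary least squares
(predicted on measured; slope, intercept, R²) and by error statistics: MAE,
the sample standard deviation (n−1) of the signed error, and that SD as a
percentage of the mean measured value. The annotation tolerance is

    tolerance = MAE + k × SD,  k = 2 by default.

The printed phrase "mean error ± 2 SD" is interpreted as MAE + 2·SD because
that is the combination the derived windows satisfy exactly; the
signed-mean alternative is a one-line change and both statistics are in the
calibration record. For CCS the inputs are per-entry residuals on a held-out
validation split. For Rt the default inputs are the cross-validation mean
MAE and the SD of the per-fold MAE — a deliberately conservative pair that
reflects fold-to-fold variability rather than per-compound scatter; the
per-compound variant is available through `calibrate_property()`.

### Database and annotation

`build_database()` emits one row per (candidate, adduct): m/z from the
monoisotopic mass and an adduct shift table derived from isotope masses
with the electron-mass correction, one Rt per metabolite (identical across
its adducts), and a per-adduct CCS. Rt predictions outside the
chromatographic window are clipped to the boundary and flagged, never
dropped. Measured standards entries merged on (metabolite, adduct) replace
predictions and are marked `source = "measured"`. Matching compares a
feature to every database row of its polarity within the m/z window (an
m/z-sorted binary-search index; the exhaustive double-loop oracle lives in
the test suite) and, per strategy, the CCS and Rt windows; all boundaries
are inclusive. Candidates are ranked by the mean of normalized errors over
the enabled dimensions with a fully deterministic lexicographic
tie-break. Features lacking CCS pass the CCS dimension by default (flagged)
rather than failing it; the strict behaviour is a strategy option.

## The synthetic generator

Real standards measurements for this kind of study are typically not
deposited, so the package ships a generator whose defaults *are* the study
conditions the rest of the package is evaluated under:

* a pool of 302 valid structures: ~95 hand-curated common metabolites and
  18 homologous series (fatty acids, diacids, acylglycines, glucosides,
  phenols, ...), spanning roughly 60–600 Da;
* true Rt = 0.7 + 16.3 · logistic(1.3 · z) min, where z is a standardized
  hydrophobicity-dominated descriptor combination (logP-led) — bounded in
  [0.7, 17.0] min like a 17-min reversed-phase gradient;
* true CCS = A_c · (M + adduct shift)^0.5 + δ_adduct, with three latent
  chemical classes (aromatic, polar, aliphatic — a deterministic function
  of the descriptors) setting A_c ∈ {10.8, 12.2, 13.6} and small per-adduct
  offsets;
* measurement noise: Rt SD 0.3 min, CCS SD 2 Å², m/z jitter 1 mDa; a
  7/204-scale fraction of compounds flagged descriptor-incomplete to
  exercise the exclusion path;
* a feature simulator that plants **true** features (database rows jittered
  well inside the windows), **decoys** (database rows within the m/z
  tolerance of a feature but displaced by 1.5× the CCS and/or Rt tolerance
  — separable by construction, so the decoy-removal property is honest
  rather than tuned), and **noise** features matching nothing.

What the generator does *not* emulate: isotope envelopes, fragmentation,
chromatographic peak shape, matrix effects, or the long tail of exotic
chemistry in real candidate databases. Passing tests therefore demonstrate
that the machinery is correct and that the error-calibration logic behaves
as designed — not that any particular accuracy will be achieved on a given
instrument.

## Numerical and design choices

* All masses are monoisotopic; m/z is reported to 4 decimals, masses to 6.
  Formulas are Hill notation; charges and isotope labels are rejected, not
  guessed. The acetate adduct accepts the vendor spelling `[M+CH3OO]-`.
* Seeds: every stochastic step (sampling, noise, fold and cluster
  assignment, grid-search folds) is a pure function of an explicit seed;
  the pipeline derives stage seeds from one master seed by fixed offsets.
* The latent-class rule in the generator was chosen over a clustering-based
  assignment so that the class is a reproducible, chemically interpretable
  function of structure. On this pool the three families are not cleanly
  silhouette-separable in full descriptor space (aromatic-vs-rest dominates),
  so the cluster-count selector is verified on constructed
  three-cluster data, and on pipeline runs k is chosen by silhouette on the
  actual feature cloud, typically landing at 2.
* Problem sizes used by the tests and the acceptance script — a 200-compound
  library (~500 CCS adduct entries), a 2,100-row database over the
  302-structure pool, 50 simulated features (40 true / 30 decoy / 10
  noise) — were chosen to mirror the scale of a realistic standards
  campaign while keeping a full run in well under a minute.
* Duplicate candidate structures under different ids are all kept (ids are
  the identity); a metabolite measured in both ESI modes contributes one Rt
  row (the mean, with a warning if modes disagree).

## Limitations

Rt models are method-specific: a model trained on one gradient predicts
nothing about another. CCS values are stored exactly as given — no
charge-state rescaling and no cross-platform (drift-tube vs travelling-wave)
correction is attempted. The rank score covers only m/z, CCS and Rt;
isotope-pattern and fragmentation scores are accepted as user-supplied
columns, never computed. The SVR-based models interpolate well inside the
training chemistry and are deliberately flagged, not trusted, outside it.
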