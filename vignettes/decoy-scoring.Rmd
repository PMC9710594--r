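---
title: "Scoring protein–protein docking decoys with decoyforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein–protein docking decoys with decoyforest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`decoyforest` rescoring treats decoy selection as binary classification:
given a docking decoy described by a numeric feature vector, predict whether
it is *correct* (CAPRI acceptable, medium or high quality) or *incorrect*.
The package covers the full workbench around that classifier — geometric
assessment against the native structure, feature computation and ingestion,
leakage-free dataset construction, the class-weighted random forest itself,
and CAPRI-style evaluation — plus a seeded synthetic generator that makes
every step testable offline. This vignette records the modelling choices,
their defaults, and what the tests do and do not establish.

## CAPRI assessment

For a decoy–native pair sharing residue numbering we compute

* **fnat**: the fraction of native inter-body residue contacts reproduced by
  the decoy. A contact is any receptor/ligand *heavy-atom* pair at distance
  `< 5` Å, collapsed to a residue pair. Contacts present only in the decoy
  are ignored (over-prediction is penalized elsewhere).
* **L-rms**: the decoy's receptor backbone (N, CA, C, O) is least-squares
  superposed onto the native receptor backbone (Kabsch, proper rotation
  enforced by flipping the smallest singular vector when det < 0); the
  transform is applied to the decoy ligand and the *unfitted* backbone RMSD
  over matched ligand residues is returned.
* **I-rms**: interface residues are defined **on the native only** — any
  residue of either body with a heavy atom `< 10` Å from the partner — and
  the matched decoy interface backbone is superposed onto the native's; the
  post-fit RMSD is reported.

Quality classes are assigned top-down from the standard ranked criteria:
high (fnat ≥ 0.5 and (L-rms ≤ 1 or I-rms ≤ 1)), medium (fnat ≥ 0.3 and
(L-rms ≤ 5 or I-rms ≤ 2)), acceptable (fnat ≥ 0.1 and (L-rms ≤ 10 or
I-rms ≤ 4)), otherwise incorrect. The table is an argument
(`capri_criteria()`), because published variants differ in detail and the
exact thresholds in use should be auditable. Monotonicity (improving any
one parameter never lowers the class) is enforced by property tests.

Decoys with a clash count (heavy-atom cross-body pairs `< 3` Å) strictly
above the per-target mean + 2 standard deviations are discarded before any
dataset is built. The standard deviation uses the sample (n − 1)
denominator; with fewer than two decoys the statistic is refused rather
than guessed.

**Numerical conventions.** All distance cutoffs use strict `<`; a pair at
exactly the cutoff is excluded. This is a determinism choice — "within
5 Å" does not specify the boundary, and ties at a floating-point boundary
are unstable under coordinate round-tripping. Hydrogens (and deuteriums)
are kept in the parsed model but excluded from contacts, interfaces,
clashes and surfaces: the clash definition is explicitly non-hydrogen, and
decoys from different engines differ in protonation, so including
hydrogens would make fnat engine-dependent. Alternate locations resolve to
the highest occupancy (first wins a tie); HETATM records and waters are
dropped at parse time. Residues are identified by (chain, author resseq,
insertion code) throughout; unmatched residues are dropped from RMSD
selections with a logged count rather than failing the batch.

## Features

The internal registry has 27 features:

* **Consensus contact score** (1): the mean ensemble frequency of the
  decoy's inter-residue contacts — for contact *c* present in *k* of *M*
  ensemble members, frequency *k/M*; the decoy's score is the mean over its
  contacts (0 if contactless). The mean, not the sum, is the default so the
  score is a conservation measure in [0, 1] independent of interface size;
  the sum variant is available behind a flag. This score is the single
  most informative feature in practice: correct decoys share contacts with
  the near-native part of the ensemble, scattered incorrect ones do not.
* **Contact-class counts** (21): residue contacts at 5 Å classified by the
  amino-acid class of the two residues over {apolar, polar, aliphatic,
  aromatic, charged} — 15 unordered class-pair counts, 5 per-class totals,
  and the overall contact count. The class table is deliberately
  overlapping (PHE is apolar *and* aromatic; HIS is polar, aromatic and
  charged); a contact counts in every applicable cell. Per-class totals
  count contacts with *at least one* member in the class — the count per
  class is not otherwise pinned down, and this reading keeps each total
  ≥ every pair count involving the class.
* **Buried surface area** (3): BSA = SASA(receptor) + SASA(ligand) −
  SASA(complex) with Shrake–Rupley SASA (probe 1.4 Å, 960 deterministic
  golden-spiral test points per atom, heavy atoms only, vdW radii C 1.70,
  N 1.55, O 1.52, S 1.80 Å). Polar BSA is the N/O-atom contribution,
  apolar the rest, so total = polar + apolar exactly. The implementation is
  validated against the closed-form buried area of two intersecting
  spheres at the discretization tolerance.
* **Non-interacting surface** (2): among residues exposed in the complex
  (relative SASA > 5% of the residue's theoretical maximum) and *not* in
  the 10 Å interface, the percentage polar and apolar by the class table.
  Exclusively charged residues (D, E, K, R) sit in the denominator of both
  percentages but in neither numerator. With no eligible residue the
  feature is missing, not zero.

External scoring-function tables (e.g. CCharPPI exports) are ingested from
CSV/TSV keyed by (target, model), outer-merged, and never recomputed. A
feature missing in more than 30% of all rows is dropped; remaining missing
cells are imputed with the per-target mean of that feature. When a target
has no observed value at all, the global mean is used — the source protocol
is silent on this case, and the global mean is the least-informative
consistent fill. Cleaning is idempotent. Normalization is the Z-score
Z = (x − μ)/σ with μ, σ fit on *training rows only* and stored in the
trained model; constant features are dropped with a warning rather than
dividing by zero.

## Datasets and splits

Only clash-surviving decoys enter datasets; targets with no correct decoy
are removed up front (they can teach nothing and poison recall estimates).
Two manifests are built per run:

* **Balanced**: per target, all correct decoys plus an equal-size uniform
  random sample (without replacement) of its incorrect decoys. If incorrect
  supply falls short, all are taken and the imbalance logged.
* **3K (capped unbalanced)**: per target, at most 600 correct decoys
  (uniform random sample when over the cap — the cap's selection rule is
  not pinned down by the protocol; "best-quality-first" would bias the
  class-conditional feature distributions, so uniform is the default) plus
  random incorrect decoys up to 3000 in total.

Splits are always by target: benchmark membership (BM4 targets train,
BM5-update targets validate) or repeated random draws of 64 validation
targets (10 repeats). Every sampling decision derives from a single run
seed through per-target substreams (a 31-bit string hash of the target id
mixed into the seed), so adding or removing one target never perturbs
another target's sample — an auditability property the tests assert
directly. The balanced builder leaves the correct class uncapped by
default; a cap argument exists because the 600-decoy cap's reach into the
balanced set is ambiguous in the source protocol.

## The forest

No random-forest package is assumed: the classifier is a self-contained
CART/Gini implementation (Rcpp) — bootstrap per tree, mtry = ⌊√p⌋ features
per node, unlimited depth, nodes below `min_samples_split` (default 10)
become leaves. Class weights (defaults 1.2 for incorrect, 0.1 for correct)
enter as per-sample weights in every impurity computation, matching the
weighted-Gini semantics of mainstream implementations. Feature importance
is the normalized mean decrease in weighted impurity; a permutation view is
available in the tests as a cross-check, and both views agree on the top
feature in the planted-signal world. Prediction follows the vote rule: each
tree votes its leaf's weighted majority, the score is the fraction of trees
voting "correct", the label is score ≥ 0.5. Everything is deterministic
given the seed (per-tree RNG streams), and a fitted model is plain data —
node tables, selected features, normalization statistics, hyperparameters —
serialized to JSON, so save/load round trips yield bit-identical scores.

**Forward selection** fits a full-feature forest, ranks features by
importance, then re-fits adding one feature at a time (highest first),
recording validation accuracy and MCC at each step; the returned selection
is the set with importance ≥ the threshold (default 0.01, the point where
the metric trace plateaus in practice). If the threshold excludes
everything, the top feature is kept with a warning.

**Tuning** is coordinate-wise by design: each hyperparameter axis (trees,
min split, the class-weight pair) is scanned over its grid with the others
held at defaults, maximizing validation MCC. Tie-breaking had to be
decided: the default value wins a tie if it is among the argmax, otherwise
the smallest (simplest) value. Ranking ties break by consensus score, then
lexicographic model id — fully deterministic output was prioritized over
any pretense of meaning in sub-resolution score differences.

## Evaluation

Precision, recall, F1, accuracy and MCC are computed from the confusion
counts with the correct class positive; incorrect-class metrics swap the
roles. Degenerate cases follow the common conventions — precision or
recall with a zero denominator reports 0 with a `degenerate` flag, F1 with
P = R = 0 is 0, MCC with any zero factor in its denominator is 0. The
top-N success rate counts, per target, acceptable-or-better /
medium-or-better / high decoys among the N top-ranked; totals count targets
with at least one hit per tier, and targets with no correct decoy anywhere
in their ensemble are flagged unreachable rather than silently deflating
the rate.

## The synthetic world

`synthetic_spec()` states the world the tests run in: per target, a
receptor and ligand built as idealized backbone helices (40 and 25
residues) packed at 9.4 Å axis separation — enough for a genuine 5 Å
contact interface (≥ 5 contacts) without clashes — residue names assigned
round-robin over the 20 amino acids with a per-target offset, 0.05 Å
coordinate jitter, and a random global placement so nothing is
axis-aligned. Decoys perturb the ligand rigidly, with per-tier magnitudes
(translation, rotation about an in-plane axis through the ligand centroid):
0.2 Å/1° (high), 1.8 Å/16° (medium), 4.5 Å/40° (acceptable), 40 Å/120°
(incorrect). These defaults were derived once from the class definitions —
e.g. the medium tier must displace the ligand enough that I-rms > 1 Å
(else it classifies high) while keeping fnat ≥ 0.3 — and are validated
distributionally: the *median* assessed class per planted tier equals the
tier, while individual boundary decoys may land one tier off. A stated
fraction (5%) of decoys are interpenetration outliers for the clash screen;
notably these reproduce all native contacts (fnat = 1), a reminder that the
clash filter, not fnat, is what rejects them.

Feature tables plant class-conditional Gaussians: by default three
informative features with a 2σ mean shift between classes, five noise
features, 2% missingness. What a green test establishes is therefore
*mechanism*, not field performance: the generator has no side chains, no
flexibility, no correlated features, no docking-engine bias, and its class
balance is chosen, not observed. Numbers obtained on it say the pipeline is
wired correctly — they say nothing about accuracy on real benchmark decoys.

**A calibration note on the single-feature bar.** With one informative
feature and equal class priors, the optimal classifier thresholds at the
midpoint and attains accuracy Φ(Δμ/2σ̃) per class; at Δμ = 2σ that is
Φ(1) ≈ 0.841, hence a Bayes-ceiling MCC of 2Φ(1) − 1 ≈ 0.683 (the AUC,
Φ(Δμ/σ√2) ≈ 0.921, is the quantity that clears 0.9 — MCC does not). An
acceptance criterion in this package's contract demands held-out MCC > 0.8
from exactly this generator; no classifier can meet it, the corresponding
test is left failing on that expectation, and the planted-signal *property*
(MCC > 0.8) is instead established with the generator's default of three
independent informative features, whose combined d′ = 2√3 gives a Bayes MCC
≈ 0.92.

## Known limitations

* PDB input only (no mmCIF), single-model files, no structure repair or
  protonation; multi-chain bodies are supported but assemblies with
  symmetry mates are not resolved.
* SASA uses fixed vdW radii by element and ignores hydrogens; absolute
  areas carry the usual ~1–3% discretization error at 960 points.
* The external-feature path ingests tables as-is; none of the published
  potentials behind them are reimplemented.
* The forest is binary; the quality tiers are used for evaluation only,
  not as a multi-class target.
* Full-scale benchmark numbers (millions of decoys, 158-feature registry)
  are out of desk-scale reach; the test surface is the synthetic world
  described above.
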