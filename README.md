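# decoyforest

Random-forest rescoring of protein–protein docking decoys, with CAPRI-style
quality assessment, consensus contact scoring, and fully offline synthetic
test data.

## The problem

Rigid-body docking programs produce 10³–10⁵ candidate poses ("decoys") per
protein–protein complex, of which typically well under 5% are anywhere near
the true interface. Scoring — singling out those few correct poses — is the
hard step. `decoyforest` implements a complete scoring workbench:

1. **Assessment.** Each decoy is compared to the native complex with the
   three CAPRI parameters:
   - *f<sub>nat</sub>* — fraction of native inter-body residue contacts
     (any receptor/ligand heavy-atom pair < 5 Å) reproduced by the decoy;
   - *L-rms* — backbone RMSD of the ligand (smaller partner) after optimal
     (Kabsch) superposition of the receptors;
   - *I-rms* — backbone RMSD over the native 10 Å interface residues after
     superposing the interfaces.

   These map onto the ranked quality classes **incorrect < acceptable <
   medium < high** ("correct" = acceptable ∪ medium ∪ high). Decoys with a
   clash count (heavy-atom pairs < 3 Å) above the per-target mean + 2 sd are
   discarded.

2. **Features.** Per decoy: the consensus (CONSRANK-style) score — the mean
   ensemble frequency of the decoy's inter-residue contacts — plus 21
   contact counts per amino-acid class, buried surface area
   (total/polar/apolar, Shrake–Rupley) and non-interacting surface
   composition; externally computed scoring-function tables (CCharPPI-style
   CSV/TSV exports) are merged in, cleaned (features missing for > 30% of
   rows dropped, the rest imputed by per-target means) and Z-score
   normalized with training-set statistics, Z = (x − μ)/σ.

3. **Datasets.** Per-target balanced manifests (all correct decoys + an
   equal random sample of incorrect ones) and capped unbalanced "3K"
   manifests (≤ 600 correct, topped up with incorrect to 3000), split by
   *target* (benchmark membership or repeated random 149/64) so no decoy of
   a validation target ever reaches training.

4. **Classifier.** A class-weighted random forest (CART/Gini, bootstrap,
   mtry = ⌊√p⌋) written in Rcpp — defaults: 100 trees, min 10 samples to
   split, class weights 1.2 (incorrect) / 0.1 (correct) — with
   importance-driven forward feature selection at a 1% importance threshold
   and coordinate-wise hyperparameter tuning on validation MCC:

   MCC = (Tp·Tn − Fp·Fn) / √((Tp+Fp)(Tp+Fn)(Tn+Fp)(Tn+Fn))

5. **Evaluation.** Per-class precision/recall/F1, accuracy, MCC, and the
   CAPRI top-N success rate with quality-tier breakdown (the
   `9/3***/5**` notation: hits / high / medium).

A seeded synthetic module generates two-helix toy complexes, rigid-body
perturbed decoy ensembles with planted quality tiers and clash outliers, and
feature tables with stated class-conditional distributions, so the whole
pipeline is testable with no external data.

## Worked example

```r
library(decoyforest)
spec   <- synthetic_spec(seed = 1, n_targets = 2,
                         tier_counts = c(incorrect = 40, acceptable = 6,
                                         medium = 4, high = 4))
native <- make_native(spec, 1)
dec    <- make_decoys(native, spec)

assessment <- assess_target(native, dec$decoys)
head(assessment[, 1:6], 4)
#>   model_id fnat  lrms irms clashes    quality
#> 1 T1_d0001    1  9.41 4.59     515 acceptable
#> 2 T1_d0002    1  9.68 4.80     559 acceptable
#> 3 T1_d0003    1  9.47 4.67     515 acceptable
#> 4 T1_d0004    0 27.32 9.63       0  incorrect
table(assessment$quality)
#> acceptable       high  incorrect     medium
#>          9          4         38          3
```

The first three rows are deliberately planted interpenetration outliers:
they reproduce every native contact (fnat = 1) yet carry hundreds of atomic
clashes — exactly what the clash screen exists for:

```r
scr <- screen_clashes(setNames(assessment$clashes, assessment$model_id))
#> clash threshold 297.2; discarded 3 of 54 decoys

ft <- featurize_target(dec$decoys)
#> <feature_table: 54 rows, 27 features (27 internal, 0 external)>
cons <- as.data.frame(ft)$CONSRANK_score
#> mean consensus score: correct 0.144 vs incorrect 0.013
```

Correct decoys share their contacts with each other and with the near-native
ensemble, so their consensus score is an order of magnitude above that of
scattered incorrect poses — which is why it dominates the forest's feature
importances. `run_synthetic_pipeline(synthetic_spec(seed = 1))` chains all
of the above into training and evaluation; the same steps are available as
subcommands (`simulate`, `assess`, `featurize`, `build-dataset`, `train`,
`rank`, `evaluate`) via

```sh
Rscript -e 'decoyforest::cli_main()' simulate --out sim/ --seed 1
```

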