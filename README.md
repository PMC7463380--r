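# dtigist

Drug-target interaction (DTI) prediction from protein evolutionary
profiles and drug substructure fingerprints, for computational chemists
and bioinformaticians screening candidate interactions before bench
validation.

## Method

A drug-target network is a bipartite graph; known interactions are the
positive class and a balanced set of sampled non-edges the negative
class. Each (drug, target) pair is described by 1393 features:

* **Drug block (881):** the PubChem substructure fingerprint, bit *k*
  flagging fragment *k* of a fixed chemical dictionary.
* **Protein block (512):** a block-GIST texture descriptor of the
  protein's position-specific scoring matrix (PSSM). The M x 20 PSSM is
  squashed entrywise through the logistic map, filtered with a bank of
  32 Gabor filters (4 octave-spaced scales x 8 orientations),

  G(x, y) = exp(−(x′² + γ²y′²)/(2σ²)) · exp(i(2π x′/λ + ψ)),
  x′ = x cos θ + y sin θ, y′ = −x sin θ + y cos θ,

  and each response-magnitude map is averaged over a 4 x 4 grid:
  16 block means x 32 filters = 512 values.

Pairs are classified by a **rotation forest** of L = 12 unpruned decision
trees. For each tree the n features are randomly split into K = 10
subsets; each subset gets a PCA basis estimated on a 75% bootstrap of
the rows; the per-subset coefficient blocks form a sparse block-diagonal
rotation matrix S_i, the tree trains on the rotated features, and the
ensemble confidence is the average of per-tree class probabilities,
λ_j(w) = (1/L) Σ_i d_ij(w S_i). Evaluation is stratified five-fold
cross-validation reporting accuracy, precision, sensitivity, MCC, AUC
and AUPR per fold and as mean ± sd.

No benchmark data are bundled; a synthetic generator plants a tunable
latent interaction signal in all three input formats (pair-list TSV,
fingerprint TSV, PSI-BLAST ASCII PSSMs) so the whole pipeline is testable
offline, and real data in those formats can be dropped in directly.

## Worked example

```r
library(dtigist)

ds <- worked_example()      # miniature 6 x 5 interaction network
ds
#> dti_dataset: 6 drugs x 5 targets, 8 known interactions (26.67% of 30 pairs)

str(dataset_stats(ds))
#> List of 6
#>  $ n_drugs              : int 6
#>  $ n_targets            : int 5
#>  $ n_positives          : int 8
#>  $ n_total_pairs        : int 30
#>  $ n_candidate_negatives: int 22
#>  $ positive_fraction    : num 0.267
```

30 possible pairs minus 8 known interactions leaves 22 candidate
negatives; balanced sampling draws 8 of them, giving 16 labeled pairs.

A small end-to-end experiment on synthetic data with a planted signal:

```r
spec <- synthetic_spec(n_drugs = 16, n_targets = 12,
                       protein_length_range = c(30, 60),
                       positive_rate = 0.3, seed = 7)
cv <- run_experiment(experiment_config(synthetic = spec, k = 5, seed = 7,
                                       outdir = "readme_run"),
                     verbose = FALSE)
print(cv)
#> 5-fold cross-validation (seed 9)
#> Fold  Accuracy (%)  Precision (%)  Sensitivity (%)  MCC (%)  AUC  AUPR
#> 1     79.17   76.92   83.33   58.54   0.8542  0.8166
#> 2     87.50   84.62   91.67   75.26   0.9549  0.9382
#> 3     95.45   91.67   100.00  91.29   0.9215  0.8484
#> 4     100.00  100.00  100.00  100.00  1.0000  1.0000
#> 5     90.91   84.62   100.00  83.21   0.9917  0.9860
#> Average 90.61 ± 7.10 87.56 ± 7.77 95.00 ± 6.67 81.66 ± 14.19 0.9445 ± 0.0531 0.9179 ± 0.0733
```

The planted latent signal is recovered well above chance (mean AUC 0.94
here); regenerating with `signal_strength = 0` drops AUC to ~0.5. The
output directory holds the per-fold table, labeled pairs, descriptors,
serialized fold models, config snapshot and stage log; re-running the
same config reproduces them byte for byte.

A thin CLI wraps the same functions
(`Rscript inst/cli/dtigist.R <simulate|gist|features|cv> ...`).

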