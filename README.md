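# specurate

Species misclassification detection and correction for genotyped germplasm
collections.

Genebanks conserve large collections of crop wild relatives whose species
labels are not fully trustworthy: morphological identification is hard,
accession histories are convoluted, and regeneration cycles propagate
errors. As collections are genotyped (resequencing SNP panels, AFLP and
other marker systems), the genotypes themselves can be used to flag and
correct wrong labels — but there is no gold-standard training set. Every
classifier has to learn from the very labels it is asked to correct.

`specurate` implements the building blocks of that curation workflow for R
users and, through a small CLI, for collection curators:

* **Five classifiers with explicit ambiguity.** For a labelled genotype
  matrix `X` (accessions × markers, dosage-coded) each accession *i* gets a
  call `ŷᵢ ∈ S ∪ {AMBIGUOUS}`:
  * `classify_1nn()` — leave-one-out 1-nearest neighbour on the
    divergent-site distance `d(i,j) = #{m : xᵢₘ ≠ xⱼₘ}` (pairwise deletion
    over missing calls);
  * `classify_3nn_conservative()` — the recommended rule: 3-NN on Euclidean
    distance over imputed codes with the query itself among its three
    neighbours (`k = 3`, minimum winning votes `l = 2`, ties for the third
    neighbour all vote). One agreeing neighbour confirms an a-priori label,
    two dissenting neighbours are needed to overturn it, and a species needs
    only two correctly labelled accessions for unambiguous
    self-confirmation;
  * `build_nj()` + `classify_nj()` — Saitou–Nei neighbour joining
    (implemented in-package) followed by the smallest-subtree rule: the
    strict majority species of the smallest clade properly containing the
    query, escalating exactly once before declaring ambiguity;
  * `classify_rf_oob()` — a 10,000-tree random forest voting only through
    the ≈ `0.368 B` trees each accession is out of bag for;
  * `fit_nb()` + `classify_nb()` — categorical naive Bayes with Laplace
    smoothing, resubstitution or leave-one-out.
* **A proximity outlier screen** (`rf_proximity()`, `outlier_scores()`):
  outlyingness `n / Σⱼ prox(i,j)²` over classmates, median/MAD-standardised
  per species, flagged above 10. Advisory only — see the vignette for why
  modal imputation inflates it.
* **A misclassification-injection benchmark** (`curate()`, `subsample()`,
  `inject_misclassifications()`, `run_grid()`): subsample each species to a
  fixed representation, corrupt a known fraction of labels, and score each
  classifier against the pre-corruption truth.
* **The comparison statistics** (`friedman_aligned_ranks()`,
  `finner_adjust()`, `posthoc_vs_control()`, `compare_classifiers()`):
  Friedman Aligned Ranks omnibus, Finner step-down correction
  `1 − (1 − p)^{m/i}`, and aligned-rank z comparisons against the
  best-performing classifier as control.
* **A synthetic collection generator** (`generate_collection()`):
  Balding–Nichols species divergence — per marker `p ~ U(range)`, per
  species `p_s ~ Beta(p(1−F)/F, (1−p)(1−F)/F)`, genotypes `Bin(2, p_s)` —
  with controllable representation, missingness and divergence `F` (the
  expected between-species FST).

## Worked example

Simulate a five-species collection, corrupt 12.5% of its labels, and ask the
conservative 3-NN rule to find the errors:

```r
library(specurate)
syn    <- generate_collection(n_species = 5, n_per_species = 8,
                              n_markers = 1000, divergence = 0.4,
                              missing_rate = 0.02, seed = 42)
labels <- inject_misclassifications(syn$labels, rate = 0.125, seed = 7)
gm     <- impute_most_common(syn$genotypes)
preds  <- classify_3nn_conservative(euclidean_distance(gm), labels)
print(preds)
#> predictions (3nn): 40 accessions, 1 ambiguous, 4 disagree with a priori
accuracy(preds, true_labels(labels))
#> accuracy 1.0000 (40 predictions, 1 ambiguous excluded)
preds[preds$call != AMBIGUOUS & preds$call != preds$a_priori,
      c("accession", "a_priori", "call", "votes")]
#>  accession a_priori call         votes
#>   sp01_002     sp05 sp01 sp01:2,sp05:1
#>   sp02_007     sp04 sp02 sp02:2,sp04:1
#>   sp03_003     sp02 sp03 sp02:1,sp03:2
#>   sp04_004     sp05 sp04 sp04:2,sp05:1
```

Five labels were corrupted; the rule corrected four outright (two
conspecific neighbours outvoting the wrong a-priori label each time) and
declined to call the fifth (`sp04_007`, votes split 1/1/1) rather than
guess. Every non-ambiguous call matches the true species. The disagreement
table is the curator-facing product: accessions whose genotype contradicts
their documentation, with the evidence attached.

The same workflow runs from a shell:

```sh
exec/specurate simulate --species 5 --per-species 8 --markers 1000 --seed 42 --out-dir demo
exec/specurate classify --matrix demo/genotypes.tsv --labels demo/labels.tsv \
    --methods 3nn,rf --seed 1 --out-dir demo   # writes disagreements.tsv
```

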