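---
title: "Curating species labels in genotyped collections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating species labels in genotyped collections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specurate)
```

## The problem

Collections of crop wild relatives carry species labels of uneven quality,
and for most taxa there is no verified reference panel to train on. The
methods in this package therefore all work *transductively*: they take the
collection's own genotypes and its own (partly wrong) labels, and ask, for
each accession, whether the rest of the collection supports its
documentation. A classifier is useful for curation exactly when it can
improve a bad label set — fix more errors than it introduces — and useless
when, like a label echo, it merely reproduces the input.

This vignette records the models, the parameter choices, and the design
decisions that were genuinely open, in enough detail to re-derive the
implementation.

## Data model

Genotypes are an accessions × markers integer matrix: ALT-allele dosage
0/1/2 for diploid SNPs, presence/absence 0/1 for dominant systems such as
AFLP, `NA` for missing. A single integer alphabet keeps every classifier
agnostic to the marker technology. Labels are a named character vector with
a provenance flag (`a_priori`, `perturbed`, `predicted`); perturbed label
sets retain their pre-perturbation originals so benchmark scoring can use
the truth.

Import filters mirror standard resequencing practice: per-genotype calls
under a read-depth floor are masked to missing *before* site-level
call-rate and minor-allele-frequency thresholds are evaluated, so depth
masking can itself disqualify a site; indel and multi-allelic records are
dropped. For dominant data, markers flagged as carrying heterozygous scores
(anomalous for a dominant system) are removed whole, then markers under the
MAF floor — removing whole flagged markers, rather than repairing cells,
is the only treatment consistent with reporting a fixed post-filter marker
count. For large panels two marker-selection routes are offered: a strict
quality filter, or uniform random thinning to a target count
(`thin_markers()`); which one helps is dataset-dependent, so both are kept
and the choice is left to the user.

Missing-data imputation (`impute_most_common()`) replaces each missing call
with its marker's modal value. It is deliberately crude — fast, assumption
free, and independent of class labels — and its known failure mode is
documented below. Modal ties break toward the lowest code; the choice is
arbitrary but must be deterministic for reproducible pipelines.

## Distances

Two dissimilarities are used, each paired with the classifiers that
conventionally use it:

* **Divergent sites** (1-NN, NJ): the count of markers at which two
  accessions differ, ignoring markers missing in either (*pairwise
  deletion*). The raw count is deliberately **not** normalised by the
  number of comparable sites. This reproduces the classical behaviour, and
  its bias is real: an accession with heavy missingness shares few
  comparable sites with everyone and therefore looks artificially close to
  everything. Results for missing-rich accessions deserve suspicion.
* **Euclidean distance on imputed codes** (conservative 3-NN; the RF and NB
  learners likewise consume the imputed matrix).

## The classifiers

**1-NN** is the baseline: each accession receives the label of its nearest
other accession, its own label never consulted. Its failure mode is
instructive — in a mutual nearest pair with one wrong label, it repairs the
wrong accession and corrupts the right one. A method that cannot beat 1-NN
is not worth deploying. Nearest-neighbour ties resolve by majority among
the tied set, ambiguous if none.

**Conservative 3-NN** includes the query itself, at distance zero, among
its three neighbours, plus every accession tied with the third. The
winning species needs the unique maximum of the votes and at least `l = 2`
of them. The asymmetry is the point: one agreeing neighbour confirms an
a-priori label, two dissenting neighbours are needed to overturn it, and
two correctly labelled conspecifics suffice for unambiguous
self-confirmation (three would be needed if the query did not vote). A
non-unique maximum is ambiguous: with the query's own vote in the set, a
tied maximum means the evidence to overturn is exactly balanced, and a
conservative rule declines to call.

**NJ smallest subtree.** Saitou–Nei neighbour joining is implemented
directly (Q-criterion minimisation with lexicographic tie-breaks, standard
branch-length formulas, negative branches clamped to zero with originals
kept in diagnostics). Classification then needs a clade structure, which an
unrooted tree does not define, so the tree is midpoint-rooted first —
deterministic, independent of input order, and exposed as an option
(`root = "none"`) for pre-rooted trees. The query takes the strict-majority
(> 50%) species of the non-query leaves of the smallest clade properly
containing it; failing that, the rule escalates exactly once to the next
enclosing clade; failing both, ambiguous. The query's own label does not
vote — a classification should not confirm itself. Both rooting and
self-exclusion were open design points: the traditional workflow reads
clades off a drawn tree by eye, which no deterministic rule reproduces
exactly; midpoint rooting and self-exclusion are the choices that make the
rule order-invariant and non-circular, and the test suite pins both.

**Random forest, out-of-bag.** The forest (10,000 trees, `mtry = ⌊√p⌋`,
gini splits, bootstrap with replacement — grown by `ranger`, single
threaded for determinism under a seed) classifies each accession using only
the trees whose bootstrap sample excluded it: with `n` accessions that is
`B(1 − 1/n)^n ≈ 0.368 B` trees, about 3,680 of 10,000, which is why the
forest is grown so large. OOB aggregation, the parameter mapping and
seeding are owned by this package; per-tree predictions are recombined with
the in-bag records so the plurality, vote fractions, and the zero-OOB
degenerate case (ambiguous) are all explicit. Plurality ties break to the
lexicographically first species.

**Categorical naive Bayes** is implemented from scratch because the
standard R implementation treats numeric predictors as Gaussian; here each
marker is categorical over the fixed genotype alphabet of the data's ploidy
mode. Laplace `alpha = 1` smooths every cell of the class × call tables;
priors are class frequencies; accumulation is in log space so `alpha = 0`
with an unseen call excludes a class (−∞) without numeric failure.
Leave-one-out mode down-dates the count tables per query rather than
refitting, which makes LOO cost almost nothing; a class emptied by the
removal drops out through its zero prior. On curated benchmark runs NB is
evaluated by resubstitution and RF by OOB (LOO is available for NB and is
the right choice when reporting unbiased accuracy on a complete dataset);
where the historical choice was ambiguous we default to the cheaper
resubstitution and expose the mode.

## The proximity outlier screen

A large forest (50,000 trees by default, so pairwise proximities are well
resolved) records how often two accessions co-terminate in a leaf. The raw
outlyingness of accession *i* in its declared class of size *n* is
`n / Σ_{j≠i} prox(i,j)²`; per class, scores are centred by the median and
scaled by the MAD (standard consistency constant; a zero MAD falls back to
no scaling with a warning), and scores above 10 are flagged. Two details
differ between published descriptions of this measure and its common
implementation: whether *n* is the class or the total sample size, and
whether the self-proximity enters the sum. The multiplicative constant
cancels under median/MAD standardisation, so only the self term matters;
this package excludes it (an accession's similarity to itself is not
evidence about its class) and the tests verify rank agreement with the
reference implementation.

The screen is advisory. Modal imputation drags missing-rich accessions
toward the majority species' genotype, so under most-common-allele
imputation the screen is prone to false positives — it may flag accessions
for their sequencing depth rather than their taxonomy. Exclusions should be
confirmed by a classifier before they are acted on.

## The benchmark

`curate()` drops species below a representation floor (default 10),
honouring an exclusion list first, so a species pushed under the floor by
exclusions disappears entirely. `subsample()` fixes representation per
species; `inject_misclassifications()` corrupts exactly
`round(rate · N)` labels (half-up rounding — the standard design uses
sixteenth rates on multiples of 16 accessions, so the product is integral
and the rounding rule is only a guard), each to a uniformly drawn *other*
species. `run_grid()` crosses representations {2, 4, 6, 8, 10}, rates
{6.25%, 12.5%, 18.75%} and 5,000 replicates — 75,000 perturbed datasets —
with every classifier in a replicate seeing the identical perturbed label
set, and scores against the *pre-perturbation* truth: the question is
whether a classifier improves a bad dataset. Scoring against the perturbed
labels is available as a diagnostic.

Seeding uses a master seed that spawns one child seed per subsample and
per injection up front, so any cell is reproducible in isolation and the
grid is bit-identical under the master seed. The `"echo"` pseudo-classifier
returns the perturbed labels unchanged and must score exactly `1 − rate`;
it anchors the harness analytically, and the suite asserts it.

Injected errors are uniform by construction. Real misclassifications are
not — morphologically similar species are confused systematically — so
benchmark accuracies are an optimistic bound for structured confusion, a
limitation inherited by any conclusion drawn from the grid.

## Statistics

Classifier accuracies are compared with the Friedman Aligned Ranks test:
observations aligned by problem means, all `kn` values ranked jointly
(mid-ranks on ties), and the statistic referred to χ²(k−1). Alignment keeps
the test powerful at small k (4–5 classifiers), where the plain Friedman
test is weak. Degenerate tables (all classifiers equal within every
problem) return T = 0, p = 1 rather than 0/0. Accuracies are grouped by
(representation, rate); each group gets an omnibus test, the omnibus
p-values are Finner-corrected across groups, and significant groups are
followed up with aligned-rank z comparisons
(`z = (R̄ⱼ − R̄₀)/√(k(kn+1)/6)`) against the classifier with the highest
mean accuracy as control, Finner-corrected over the k−1 comparisons. The
grouping itself was ambiguous (one omnibus over all cells versus one per
group); per-group is the default and the pooled mode is offered
(`by = "overall"`). The z denominator is the exact variance of a difference
of mean ranks in a joint ranking of `kn` values partitioned into k groups
of n, and the suite checks the omnibus against an exhaustive sign
permutation at k = 2 and its type-I rate (within [0.03, 0.07] at nominal
0.05 over 2,000 null tables of 15 × 5).

Accuracy excludes ambiguous calls from numerator and denominator —
declining to call is neither right nor wrong — and is reported as undefined
(not zero) when every call is ambiguous. Accuracy is equitable only under
equal representation, which the benchmark enforces; per-species accuracies
and the fractional confusion matrix cover the imbalanced case.

## The synthetic generator

`generate_collection()` draws, per marker, an ancestral frequency
`p ~ U(0.05, 0.5)`, then per species `p_s ~ Beta(p(1−F)/F, (1−p)(1−F)/F)` —
the Balding–Nichols model, chosen because two parameters give tunable,
realistic species structure and `F` is interpretable as the expected
between-species FST (the tests verify realised Weir–Cockerham FST tracks
`F`). Genotypes are binomial in `p_s`; markers are unlinked, which matches
the independence assumption NB makes anyway; missingness is i.i.d.

Defaults are the validation conditions used throughout: 8 species × 10
accessions and strong divergence `F = 0.5`, the regime of well-separated
congeners where a reliable curator rule should push accuracy near 1; the
default 2,000 markers are enough that between-species signal dominates
sampling noise at that `F` while keeping every distance and forest
computation fast at desk scale. What the generator does *not* emulate —
linkage, hybrids and introgression, structured confusion between sister
taxa, depth-correlated missingness — bounds what passing tests show: they
validate the machinery and its contracts, not performance on any real
collection.

## Degenerate inputs and numerical conventions

All-missing marker columns are an imputation error naming the marker; a
pair of accessions with zero comparable sites is a distance error naming
the pair; an empty post-filter matrix is a distinct "empty result"
condition (CLI exit code 2), not a silent success. NJ requires ≥ 3
accessions and a symmetric matrix; 3 taxa resolve by closed form. Posterior
and plurality ties break lexicographically everywhere a deterministic
answer is required; ambiguity, not tie-breaking, is the answer where the
rule itself says the evidence is balanced (3-NN, NJ, 1-NN). Species of size
one get undefined (never flagged) outlier scores. `round(rate · N) = 0`
returns labels unchanged with a warning.

## Problem sizes in the test suite

The suite validates at reduced but structurally faithful sizes: forests of
200–2,000 trees except where OOB exposure itself is under test (10,000
trees over 200 accessions), grids of a few replicates except the full
75,000-perturbation enumeration (labels only, no classifiers), and
synthetic collections up to 8 species × 10 accessions × 2,000 markers for
the recovery check (conservative 3-NN ≥ 0.95 accuracy under 6.25% injected
error at `F = 0.5`, and at least as accurate as NJ). These sizes were
chosen so the whole suite exercises every contract in well under a minute
of compute while keeping each statistical check's sampling error small
relative to its asserted margin.
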