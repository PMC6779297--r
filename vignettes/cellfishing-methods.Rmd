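---
title: "Methods: similarity-based cell-line sensitivity prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity-based cell-line sensitivity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Given a query compound, which cancer cell lines is it likely to inhibit?
`cellfishing` answers this with the simplest instrument that respects the
molecular similarity principle: structurally similar compounds tend to show
similar biological activity. For each cell line $j$ with a set of compounds
known to be *sensitive* (growth inhibition of at least 50% at a
concentration of at most 10 µM), the query $q$ receives the score

$$ s_j(q) \;=\; \frac{1}{n}\sum_{i \in \mathrm{top}_n(j,q)} T_c\!\left(q, x_i\right), $$

the mean Tanimoto coefficient between the query's circular Morgan
fingerprint and its $n$ most similar sensitive compounds of that cell line
(default $n = 3$). The pair is called sensitive when $s_j(q)$ reaches a
similarity cutoff (default 0.25, inclusive). No model is fitted; the
reference data *is* the model, which makes the approach trivially
incremental as activity databases grow.

The comparator is a per-cell-line support vector machine with an RBF kernel
on the same 1024-bit fingerprints, trained after an undersampling step that
balances the sensitive/resistant classes, with $C$ and $\gamma$ chosen by
grid search under internal cross-validation.

## Curation of raw activity data

`build_lcla_database()` turns a raw assay table into labeled
ligand–cell-line associations (LCLAs) by applying, in order:

1. endpoint filter — only IC50, GI50 and CC50 measurements are admitted;
2. relation filter — only `=` (or empty) relations by default; censored
   (`>`/`<`) values cannot be compared against a fixed threshold. An
   optional policy admits `>` records above 10 µM as resistant evidence;
3. unit conversion to mol/L (`nM`, `uM`/`µM`, `mM`, `M`);
4. salt/mixture handling — only the largest fragment of a dot-disconnected
   SMILES is kept (most heavy atoms; ties by heavy-atom mass, then by
   lexicographic canonical SMILES). The dot is treated as the fragment
   separator; cross-fragment ring closures (`C1.C1`) are not supported;
5. structure-based identity — input ids whose canonical largest fragments
   coincide are merged under one key (the lexicographically smallest id),
   so replicate agreement operates on structures, not naming accidents;
6. sensitivity labeling — sensitive iff concentration ≤ 1e-5 M, boundary
   included;
7. replicate resolution — all assays for a pair, pooled across the three
   endpoint types, must agree; conflicted pairs are discarded;
8. cell-line filter — cell lines with fewer than 10 sensitive compounds
   are dropped entirely.

Each stage logs its drop count in an audit (`db$audit`). The pipeline is
idempotent and order-invariant, which the test suite asserts.

## Fingerprints

No installed R package computes hashed circular Morgan fingerprints at
radius 8 (ECFP16), so the package implements them directly on molecular
graphs parsed by OpenBabel (via ChemmineR/ChemmineOB). Atom identifiers
start from invariants (element, heavy degree, bond-order sum, formal
charge) and are iteratively re-hashed with the sorted (bond order,
neighbour identifier) list for `radius` rounds; all identifiers are folded
into `n_bits` (default 1024) by modulus. SMILES are canonicalized before
graph extraction, so any two spellings of a molecule give identical bits —
a property the tests assert, along with determinism. Bit patterns are
*not* exchangeable with other toolkits (hash functions differ); all
similarity statements in the package are internally consistent, which is
what the method requires.

Tanimoto similarity is set arithmetic over bits, with the convention
$T_c = 0$ when both vectors are empty (unreachable for real molecules).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `radius` | 8 | Morgan radius (2/4/8 ↔ ECFP4/8/16); 8 is the most resolving |
| `n_bits` | 1024 | folded fingerprint length (bits) |
| `n_top` | 3 | neighbours averaged in the similarity score |
| `cutoff` | 0.25 | similarity decision threshold, inclusive; useful range 0.20–0.30 |
| `min_sensitive` | 10 | sensitive compounds a cell line needs to stay in the database |
| `min_per_class` | 20 | per-class minimum for SVM eligibility |
| `ratio` | 1.2 | imbalance tolerance (majority ≤ 1.2 × minority) |
| `height` | 4.5 | Ward tree cut height for the balancing clusters |

Raising the cutoff prunes sensitive calls monotonically: calls at a higher
cutoff are a subset of calls at a lower one, so the macro true-positive
rate can only fall and the true-negative rate only rise. This subset
property is asserted exactly in the tests, not merely observed.

## Class balancing

A cell line is unbalanced when the majority class exceeds 1.2 times the
minority (boundary exclusive: exactly 1.2× is balanced; the comparison
carries a 1e-9 absolute guard so binary floats cannot flip exact
boundaries such as 6 vs 5). The majority class is Ward-clustered
(`stats::hclust`, `ward.D2`, matching the squared-update criterion of the
common scientific-Python implementation) on the Tanimoto distance matrix
and the tree is cut at height 4.5. With $N_c$ clusters and $N_m$ minority
compounds:

* $N_c < N_m$: take from each cluster a quota proportional to its size
  (largest-remainder apportionment, capped at cluster size), picking the
  most central compounds first (smallest summed within-cluster distance;
  ties by id);
* $N_c \ge N_m$: re-cut the same tree into exactly $N_m$ clusters and take
  each cluster's medoid. A mean bit vector is not a compound, so
  "centroid" means medoid throughout; at $N_c = N_m$ re-cutting the tree
  reproduces the height-cut partition, so this boundary case degrades
  gracefully to one medoid per existing cluster.

Two caveats are deliberate. Ward's criterion assumes Euclidean geometry
and Tanimoto distances are not Euclidean; the procedure is used as stated
rather than "corrected", because fidelity to the published protocol
matters more than geometric orthodoxy here. And the cut height is in the
units of the implementation's Ward criterion, which differ across
linkage conventions; the height is therefore an exposed parameter, and
the proportional/centroid branch split observed on any particular dataset
depends on it.

## SVM training

`train_cell_svm()` grid-searches $C \in 2^{-5}..2^{15}$ and $\gamma \in
2^{-15}..2^{3}$ by internal $k$-fold CV accuracy (default 5-fold; fold
assignment seeded and restored afterwards), breaking ties toward the
smallest $C$ then $\gamma$, and refits on all rows with the winner. The
default grid strides exponents by 4 (30 points); `svm_grid(step = 2)`
gives the classical fine grid. At the data sizes this package targets the
accuracy surface is flat enough that the coarse stride selects equivalent
models in a fraction of the time; the stride is a parameter, not a
constant. Fingerprint features are already binary, so no scaling is
applied. Decision values are re-oriented so positive always means
sensitive, independent of libsvm's internal class order.

## Validation

**Cross-validation.** One global compound-level partition (default 10
folds) is shared by both methods and all cell lines, so the same held-out
compounds are scored everywhere. Per fold, the similarity reference — and,
for the SVM, the balancing and grid search — is rebuilt from training
compounds only. Confusion counts accumulate across folds and the macro
metrics average per-cell rates:

$$\langle TP\rangle = \frac{1}{N_c}\sum_j \frac{TP_j}{N_j^{AC}},\quad
\langle TN\rangle = \frac{1}{N_c}\sum_j \frac{TN_j}{N_j^{RC}},\quad
\langle ACU\rangle = \frac{1}{N_c}\sum_j \frac{TP_j+TN_j}{N_j^{AC}+N_j^{RC}},$$

with $N_j^{AC}$/$N_j^{RC}$ the known sensitive/resistant compound counts
of cell line $j$. Cells with a zero denominator in a given rate are
excluded from that rate's average only (possible on synthetic fixtures;
impossible for SVM-eligible cells). Every `cv_result` carries an audit of
per-fold reference or training ids so leakage can be asserted, and is
asserted, by id intersection.

**External validation** evaluates new compounds (structural absence from
the reference is enforced, by canonical largest-fragment SMILES, as a hard
error) across the *interaction* space: micro TP/TN rates weight every
known pair equally, plus compound coverage (fraction of queries with at
least one sensitive call) and TP_C/TN_C restricted to covered compounds.
Below-cutoff predictions count as resistant calls in confusion matrices,
while coverage is the separate compound-level flag — the dual convention
that lets uncovered compounds contribute true negatives but no true
positives. The combined strategy keeps similarity predictions for covered
compounds and falls back to the SVM for the rest.

## The synthetic data generator

`simulate_dataset()` provides the package's study conditions without any
download: compounds are built by decorating an internal pool of 24
drug-like two-ring cores with small substituents, so each scaffold family
is a set of close analogs; sensitivity is assigned at the (scaffold, cell
line) level with probability 0.5 and inherited by members with 5% label
noise; raw tables then re-encode labels as log-uniform concentrations
(sensitive in [10 nM, 10 µM], resistant in (10 µM, 1 mM]) with 20%
replicates, 5% conflicting assays, 10% salt forms and 2% off-type (EC50)
rows. Defaults: 12 scaffolds × 8 analogs × 12 cell lines — small enough
that the full test suite runs in about two minutes, large enough that
every pipeline rule is exercised. `generate_external_queries()` emulates
a later database release: new analogs of known scaffolds (labels
inheriting the reference tendencies) plus entirely new chemotypes from
held-back cores, which is what makes external coverage land strictly
between 0 and 1 and decay with the cutoff, as it does on real data.

What the generator does *not* emulate: realistic medicinal-chemistry
property distributions, activity cliffs, assay-protocol heterogeneity,
and the heavy-tailed compound-per-cell-line counts of real databases.
Passing tests therefore demonstrate the correctness of the machinery and
the qualitative behaviour of the method under the similarity principle —
not quantitative performance on any real screening collection.

## Numerical and design choices

* The decision rule is inclusive (`score >= cutoff`); ties among
  similarities at the top-$n$ boundary cannot affect the mean and need no
  breaking.
* Fewer than `n_top` references (possible only in edge-case fixtures,
  since curation guarantees ≥ 10 sensitive compounds per cell line) are
  averaged as-is rather than refusing the prediction.
* With self-exclusion on, a query structurally identical to a reference
  compound is removed from its own reference lists, by canonical SMILES
  rather than id, so duplicated structures cannot leak.
* Chance level of the macro accuracy: under a label permutation the
  expected $\langle ACU\rangle$ is
  $\frac{1}{N_c}\sum_j[(1-p_j) + \frac{s_j}{n_j}(2p_j-1)]$ with $p_j$ the
  sensitive prevalence and $s_j$ the method's sensitive-call count for
  cell $j$; it equals 0.5 only when prevalences sit at 0.5. The
  permutation baseline in the test suite therefore shuffles the label
  column globally — which pins every $p_j$ near the global 0.5 — rather
  than within cell lines, where uneven prevalences (0.25–0.66 on the
  standard fixture) would bias the null upward through the
  prevalence–call-rate coupling.
* All randomness (generator, folds, internal SVM CV) flows through
  explicit seeds, and seeded code restores the caller's RNG state.

## Problem sizes used by the shipped analyses

The test suite and the acceptance analysis run the standard conditions (96
compounds, 12 cell lines, ~1100 curated pairs), a reduced fixture for SVM
paths (48 compounds, 5 cell lines), 10-fold CV, a 3 × 3 hyperparameter
grid for SVM drivers, and 52 external query compounds (36 analogs + 16
new-chemotype). These sizes are the package's chosen demonstration scale;
every driver accepts arbitrarily larger inputs, and `read_pair_table()`
ingests externally curated association tables (e.g. ChEMBL extracts)
directly into the same machinery.

## Known limitations

* Fingerprint bits are implementation-specific; do not mix caches across
  packages or versions.
* Ward on Tanimoto distances is a faithful but geometrically impure
  protocol (above); cluster counts at a fixed height are not comparable
  across linkage implementations.
* The similarity method cannot cover genuinely novel chemotypes — that is
  its defining trade-off, quantified by the coverage column and mitigated
  by the combined strategy.
* Censored activity values are discarded by default; the
  `gt_resistant` policy recovers some of them under an explicit
  assumption.
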