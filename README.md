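# cellfishing

Ligand-based prediction of compound–cell-line sensitivity for R.

## The problem

Screening a compound against hundreds of tumour cell lines is expensive;
knowing *which* cell lines are worth assaying is not. `cellfishing`
implements "cell fishing": given a query structure, rank every cell line by
the query's average Tanimoto similarity to the top-*n* compounds already
known to inhibit that cell line (≥ 50% growth inhibition at ≤ 10 µM, from
IC50/GI50/CC50 data), and call the pair *sensitive* when that score reaches
a similarity cutoff:

    s_j(q) = mean of the n largest Tc(q, x_i), x_i sensitive for cell line j
    predict sensitive  ⇔  s_j(q) ≥ cutoff        (defaults: n = 3, cutoff = 0.25)

Fingerprints are hashed circular Morgan fingerprints (radius 2/4/8 ↔
ECFP4/8/16; default radius 8, 1024 bits). The package also provides the
machine-learning comparator — one RBF-kernel SVM per cell line, trained
after hierarchical-clustering undersampling of the majority class (Ward on
Tanimoto distances, proportional or medoid selection) with grid-searched
C/γ — plus the curation pipeline that turns raw activity tables into a
labeled association database, a synthetic data generator built on the
similarity principle, and cross-/external-validation drivers with
per-cell-line macro metrics and interaction-space micro metrics.

It is aimed at cheminformaticians and screening groups who want a
transparent, incrementally updatable baseline (the reference data *is* the
model) next to, or combined with, learned models.

## Worked example

```r
library(cellfishing)

# synthetic study conditions: 12 scaffold families x 8 analogs, 12 cell
# lines, scaffold-level sensitivity with 5% label noise, replicate/conflict/
# salt artifacts in the raw table
sim <- simulate_dataset(generator_config(seed = 11))
db  <- build_lcla_database(sim$raw)   # curation: filters, salts, conflicts
db
#> Curated LCLA database
#>   cell lines: 11
#>   compounds:  96
#>   pairs:      1004 (504 sensitive, 500 resistant)

# 10-fold cross-validation of the similarity method
cv <- cross_validate(db, "similarity", k = 10, seed = 3, radius = 8,
                     cutoff = 0.25)
cv
#> 10-fold CV, similarity method (cutoff 0.25): <TP> = 0.569, <TN> = 0.950,
#> <ACU> = 0.765 over 11 cell lines
```

`<TP>` and `<TN>` are per-cell-line true-positive and true-negative rates
averaged over cell lines: at cutoff 0.25 the method recovers 57% of held-out
sensitive associations while calling 95% of resistant ones correctly. One
curated cell line (CELL11) fell below the 10-sensitive-compound floor and
was dropped. The stringency trade-off is the cutoff sweep:

```r
sweep_cutoffs(db, radii = 8, cutoffs = seq(0.20, 0.35, 0.05), k = 10, seed = 3)
#>   radius cutoff mean_TP mean_TN mean_ACU n_cells
#> 1      8   0.20  0.8130  0.8457   0.8392      11
#> 2      8   0.25  0.5689  0.9504   0.7650      11
#> 3      8   0.30  0.3341  0.9838   0.6609      11
#> 4      8   0.35  0.0429  1.0000   0.5234      11
```

Raising the cutoff monotonically trades sensitive-call recall for
confidence — the sensitive calls at each cutoff are a strict subset of the
calls at any lower cutoff. Fishing for a new compound:

```r
ref  <- similarity_reference(db, radius = 8)
pred <- fish(c(query = "O=C(Nc1ccccc1)c1ccccc1CCO"), ref, cutoff = 0.25)
head(pred[pred$label == "sensitive", ])  # cell lines predicted sensitive
subset(pred, covered)                    # coverage flag per compound
```

SVMs and the combined strategy (similarity where covered, SVM elsewhere):

```r
models <- train_cell_svms(db, min_per_class = 20, seed = 5)
both   <- combined_predict(c(q = "c1ccc2ccccc2c1CCN"), ref, models)
```

The command line mirrors the R API:

```sh
exec/cellfishing simulate --out fixtures --seed 2
exec/cellfishing curate   --in fixtures/raw_activity.csv --out curated.csv
exec/cellfishing fish     --query queries.smi --reference curated.csv \
                          --radius 8 --cutoff 0.25 --out predictions.csv
```

## Using real ChEMBL data

No database connection is attempted by the package. Against a local
ChEMBL MySQL dump, a raw activity table with the expected columns can be
extracted with a query of this shape and fed to
`parse_activity_table()` / `build_lcla_database()`:

```sql
SELECT md.chembl_id            AS compound_id,
       cs.canonical_smiles     AS smiles,
       cd.chembl_id            AS cell_line_id,
       act.standard_type       AS assay_type,
       act.standard_value, act.standard_units, act.standard_relation
FROM activities act
JOIN assays a             ON act.assay_id = a.assay_id
JOIN cell_dictionary cd   ON a.cell_id = cd.cell_id
JOIN molecule_dictionary md ON act.molregno = md.molregno
JOIN compound_structures cs ON act.molregno = cs.molregno
WHERE act.standard_type IN ('IC50','GI50','CC50')
  AND act.standard_value IS NOT NULL;
```

Already-curated pair tables (compound, SMILES, cell line, label) load with
`read_pair_table()` (column aliases supported) and `lcla_from_pairs()`.
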