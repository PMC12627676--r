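# spliceclone

Clone-aware single-cell analysis of *SF3B1* mis-splicing and the bone
marrow niche.

In myelodysplastic syndromes (MDS), mutations in the splicing factor
*SF3B1* make cells use cryptic 3' splice sites at a characteristic set of
mis-splicing events. Single-cell RNA-seq rarely captures the mutant
allele itself, but it does capture those junctions — a few events per
cell. `spliceclone` turns that footprint into per-cell genotype calls and
carries them through the downstream questions of a bone-marrow niche
study. It is aimed at computational biologists analyzing single-cell
cohorts of clonal hematopoiesis (CHIP) and MDS donors.

The package provides:

* **Per-cell clone classification.** The feature is the cryptic-usage
  fraction `u = cryptic / (cryptic + canonical)` per mis-splicing event,
  missing (not zero) where the event has no reads. A weakly supervised
  L2-penalized logistic regression is fitted with each cell inheriting
  its donor's *SF3B1* status as the label, on mean-imputed usage of cells
  covering ≥ 2 events. The decision threshold is the `(1 − α)` empirical
  quantile of scores of held-out wild-type-donor cells, so the per-cell
  false-positive rate is controlled at the target `α = 10%`.
* **Pseudobulk differential expression** between predicted clones:
  donor × genotype count sums, a ≥ 2 fragments-per-million filter in at
  least half the donors of either group, and a per-gene negative-binomial
  Wald test (median-of-ratios size factors, Pearson-matched moment
  dispersion, donor as covariate, Benjamini–Hochberg correction).
* **Niche signature scores**: control-gene-binned module scores on
  log-normalized expression, and per-condition Pearson correlation
  between two scores with the Student's t-test for a correlation
  coefficient.
* **Composition testing**: probit-transformed proportions and one-vs-rest
  Fisher exact enrichment of each cell type versus Control, BH-corrected.
* **Ligand–receptor interaction counting**: within-donor sender–receiver
  cell pairs scored by ligand × receptor expression products, a ≥ 5
  nonzero-interaction pair filter, normalization by the number of
  possible cell pairs per donor, and Fisher tests for condition shifts.
* **A synthetic cohort generator** with full ground truth (genotypes,
  per-event cryptic-usage probabilities, true fold changes, true
  composition), emulating a 3 wild-type + 4 mutant-donor bone-marrow
  cohort, so the whole pipeline is testable without patient data.

## Worked example

```r
library(spliceclone)

cohort <- simulate_cohort(sim_config(seed = 1))
usage  <- splice_usage(cohort)
model  <- clone_fit(usage,
  donor_labels = setNames(cohort$donors$mut_status, cohort$donors$donor),
  cell_donor   = setNames(cohort$cells$donor, cohort$cells$cell_id),
  seed = 1)
model
#> Clone classifier (weak-label ridge logistic regression)
#>   events: 50; fit cells: 2200; lambda: 1
#>   threshold tau = 0.6758 at target FPR alpha = 0.10 (600 calibration cells)

calls   <- predict(model, usage)
metrics <- evaluate_calls(calls, cohort)
metrics$confusion
#>      call
#> truth  MUT   WT
#>   MUT  971    1
#>   WT   190 1638
```

The model separates the clones essentially perfectly (AUC 1.000,
sensitivity 0.999) while the false-positive rate among truly wild-type
cells, 190/1828 = 10.4%, sits at the calibrated 10% target — the
threshold trades specificity for a guaranteed error rate, not for
accuracy.

Differential expression between the *predicted* clones in erythroid
progenitors:

```r
ery <- cohort$cells[cohort$cells$cell_type == "EryPr", ]
ery$genotype <- calls$call[match(ery$cell_id, calls$cell_id)]
ery <- ery[ery$genotype %in% c("MUT", "WT"), ]
pb <- pseudobulk(cohort$expression, ery)
de <- nb_de_test(pb, filter_fpm(pb))
de
#> Differential expression: 1000 genes tested, 40 at padj < 0.05
#>     gene   lfc    se stat        p     padj
#> 1  G0043 0.782 0.134 5.83 5.46e-09 2.75e-06
#> 2  G0045 0.757 0.130 5.83 5.49e-09 2.75e-06
#> 3  G0059 0.704 0.126 5.57 2.52e-08 8.40e-06
```

The top genes are true simulated DE genes (G0001–G0100 carry a true
log2FC of 1). Estimates around 0.7–0.8 rather than 1.0 show the expected
attenuation from classification error: the ~10% of wild-type cells called
mutant dilute the mutant pseudobulk. Grouping by the simulator's true
genotype instead recovers the fold change within ±0.05 (see the test
suite).

`run_pipeline(sim_config())` chains every stage — simulation, usage,
classification, DE, signature scores, composition, interactions — and
returns a reproducible run report.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from a fresh simulation of the default synthetic cohort, the
empirical per-cell false-positive rate among held-out wild-type-donor
cells after fitting and calibrating the clone classifier at its default
10% target, and writes it (in percent, with the number of evaluated
cells) as JSON.
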