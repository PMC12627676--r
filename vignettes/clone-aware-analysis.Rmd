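---
title: "Clone-aware single-cell analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-aware single-cell analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceclone)
```

# The problem

Myelodysplastic syndromes (MDS) and clonal hematopoiesis (CHIP) are driven
by somatic mutations in hematopoietic stem and progenitor cells (HSPCs).
Mutations in the splicing factor *SF3B1* leave a transcriptomic footprint:
mutant cells preferentially use cryptic 3' acceptor splice sites at a
characteristic set of mis-splicing events. In single-cell RNA-seq the
mutant allele itself is rarely captured, but the cryptic junctions are —
sparsely, a few events per cell. `spliceclone` aggregates that footprint
into a per-cell genotype call and carries the calls through the
downstream comparisons a bone-marrow niche study needs: differential
expression between predicted clones, niche signature scores and their
correlation, cell-type composition shifts, and ligand–receptor
interaction counting. A seeded synthetic cohort generator with full
ground truth makes every step testable without patient data.

# The clone classifier

## Feature: cryptic-usage fraction

For event $e$ in cell $c$ with cryptic junction reads $x_{ec}$ and
canonical reads $n_{ec}$, the feature is the bounded, PSI-like usage
fraction

$$u_{ec} = \frac{x_{ec}}{x_{ec} + n_{ec}},$$

defined only where $x_{ec} + n_{ec} > 0$. Zero coverage is *missing*,
not zero: absent reads say nothing about splice-site choice. The signed
alternative $(x - n)/(x + n)$ is an affine transform of $u$ and yields
the same classifier; the bounded form keeps calibration simple.

## Weak labels and the penalized fit

No per-cell genotype truth exists in real data, so the model is weakly
supervised: every cell inherits its donor's sample-level *SF3B1* status.
Labels of mutant-donor cells are noisy — a donor with clone fraction
$f < 1$ contributes truly wild-type cells labeled mutant — but labels of
wild-type-donor cells are clean. The classifier is an L2-penalized
logistic regression

$$\min_{w, b}\; \sum_i \log\!\left(1 + e^{-y_i (w^\top u_i + b)}\right)
  + \frac{\lambda}{2}\lVert w \rVert^2$$

fitted by exact Newton/IRLS iterations (tolerance $10^{-8}$ on the
largest coefficient update, 100-iteration cap, non-convergence flagged).
The intercept is unpenalized. Label noise shifts the intercept and
attenuates the weights but, because it is one-sided, preserves the
ranking of scores — which is all the calibrated threshold needs.
$\lambda$ defaults to 1 on raw usage fractions (they already live in
$[0,1]$); standardization is available behind a flag.

Before fitting, cells must cover at least `min_events = 2` mis-splicing
events; remaining missing entries are filled by *mean imputation* — the
event's mean usage over the cells where it is covered, computed over all
cells rather than per donor (the simplest reading of mean imputation).
Events covered nowhere carry no information and are dropped with a
warning. The per-event means are stored in the model and reused when
scoring new cells, so prediction does not depend on the composition of
the prediction batch.

## Calibration to a target false-positive rate

Wild-type-donor classifiable cells are split 50/50 (seeded): one half
joins the mutant-donor cells in the fit, the other half is reserved for
calibration and never enters the fit. The threshold is the
$(1-\alpha)$ empirical quantile of the calibration scores with ties
resolved upward, so that with the strict `score > tau` rule at most a
fraction $\alpha$ (default 0.10) of calibration cells is called mutant.
A score exactly at the threshold is a wild-type call — the conservative
side. Calibration pools wild-type donors rather than averaging per
donor; with few donors the pooled quantile is far more stable.

The empirical false-positive rate is reported on the wild-type half that
did *not* set the threshold. Those cells did appear in the fit (with
correct labels), which, if anything, pulls their scores down slightly;
the reported rate is therefore marginally optimistic for brand-new
wild-type donors, and conservative with respect to the $\le \alpha$
contract being checked.

Cells under the coverage filter are still scored — score distributions
stay inspectable — but are always reported `unclassified` and excluded
from all rates.

# Pseudobulk differential expression between clones

Raw counts are summed per donor × predicted genotype within the cell
type of interest (erythroid progenitors by default), which removes the
pseudoreplication of cell-level tests. Genes enter the test only if they
reach 2 fragments per million (count / group library size × 10⁶) in at
least half of the donors of either genotype group; for odd donor counts
the ceiling applies (the stricter reading).

Each gene is tested with a negative-binomial GLM: log link, log size
factor offset (DESeq-style median-of-ratios factors, computed on genes
expressed in every group, with a library-size fallback below 10 usable
genes), design `~ genotype + donor`, and a Wald test on the genotype
coefficient with Benjamini–Hochberg adjustment. No effect-size shrinkage
is applied, so estimated log2 fold changes are directly comparable to
simulated truth.

The dispersion is a per-gene moment estimate by *Pearson matching*: the
$\alpha$ at which the Pearson chi-square
$\sum_g (y_g-\hat\mu_g)^2 / (\hat\mu_g(1+\alpha\hat\mu_g))$ equals the
residual degrees of freedom, floored at $10^{-8}$. The naive moment
estimator $\sum((y-\hat\mu)^2-\hat\mu)/\sum \hat\mu^2$ ignores the
parameters consumed by the design (typically 8 columns for 11 groups)
and is badly downward-biased there, which makes the Wald test
anti-conservative; Pearson matching restores calibration (verified by
the permutation-null uniformity test in the acceptance suite).

# Niche signature scores and their correlation

Counts are log-normalized per cell, $\ln(1 + 10^4\,x/\text{libsize})$ —
a deliberate simplification of the regularized-NB normalization used on
patient data, because the object under test is the scoring algorithm,
not the normalization. The signature score is the canonical
control-gene-binned module score: genes are ranked by mean normalized
expression and cut into `n_bins = 24` equal-frequency bins (rank ties
broken by gene name, so scores are invariant to input ordering); each
signature gene draws `n_ctrl = 100` control genes with replacement
(seeded) from its bin; the per-cell score is the mean over signature
genes minus the mean over the pooled control draws. The bin/control
defaults are the method's canonical values; they are not stated in the
source study. With no coherent program the score centers on zero by
construction.

The association between two scores (inflammation and HSPC support) is
summarized per condition by the Pearson correlation coefficient with the
two-sided Student's t-test, $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$
degrees of freedom. Zero-variance scores yield `NA` rather than an
error.

# Composition and interactions

Cell-type composition is tallied per condition within a general
population, displayed on the probit scale
($\Phi^{-1}$ of the proportion, clamped to $[1/(2N), 1-1/(2N)]$ so
empty categories stay finite), and tested one-vs-rest: for each cell
type, a 2×2 Fisher exact test of this-type-vs-rest against
condition-vs-Control, BH-adjusted across the cell types, `padj < 0.05`
flagged. Cells are pooled across donors within condition, matching the
cell-level test of the source framework; this ignores donor-level
pseudoreplication, which is why the composition counts can also be
split per donor for a more conservative analysis.

Ligand–receptor interaction scoring forms sender–receiver cell pairs
*within each donor* (exhaustive by default; a seeded uniform subsample
behind `max_pairs` for very large populations — note the normalization
below then becomes approximate). A pair's score for LR entry $(l, r)$ is
the product of normalized ligand expression in the sender and receptor
expression in the receiver. A pair's "interactions inferred" is its
count of strictly positive LR scores; pairs with fewer than 5 are
discarded. Retained-pair counts are normalized by the number of possible
pairs — the product of the donor's sender-type and receiver-type cell
counts, minus self-pairs when the two sets overlap (a cell never pairs
with itself) — and condition-level values pool donors as a ratio of
sums. Condition shifts in a sender–receiver pair's usage are tested with
a two-sided Fisher exact test on `[retained, possible − retained] ×
[condition A, condition B]`, reporting the sample odds ratio.

# The synthetic cohort: what it emulates, what it does not

`sim_config()` defaults state the world the analyses assume, mirroring
the analyzed cohort shape of 3 wild-type-labeled and 4 mutant-labeled
donors (the full 3 Control / 3 CHIP / 4 MDS structure is available via
the `conditions` argument, CHIP donors being wild-type for *SF3B1*):

* 400 cells per donor; 50 mis-splicing events (the real event list size
  is not public; 50 is a configurable stand-in).
* Genotype: Bernoulli(clone fraction 0.6) in mutant donors, wild-type
  otherwise.
* Junction counts: total reads per event per cell ~ Poisson(0.6) —
  plain Poisson, sparsity controlled by the rate alone, enough for the
  ≥2-event filter to bind (about 45% of entries covered, median ~23
  covered events per cell); cryptic reads ~ Binomial(total, ψ), with
  ψ₀ = 0.02 in wild-type and ψ₁ = 0.35 in mutant cells. An optional
  Beta concentration jitters ψ per event (off by default).
* Expression: negative binomial with dispersion 0.1 (a typical
  pseudobulk-scale value), lognormal baseline means (median ~2 counts),
  lognormal per-cell depth factors (sd 0.25 on the log scale); 100 of
  1000 genes carry a true log2 fold change of 1 in mutant cells; 25
  further genes carry a cell-type signature effect (log2 fold 1 in
  iMSCs — "additive mean shift" realized multiplicatively on the NB
  mean, i.e. additively on the log scale, the natural scale for counts).
* Cell types: drawn per condition from stated simplex vectors in which
  inflammatory MSCs expand (5% → 30%) and Pre-B and adipogenic CAR cells
  shrink from Control to MDS.

Deliberately *not* simulated: ambient RNA, doublets, batch effects, UMI
duplication, donor-level expression heterogeneity beyond depth, and
mutation-associated changes in splice-event coverage. A green test on
this generator establishes that the algorithms recover the stated
statistical structure at the stated sizes — not that they are robust to
every artifact of real droplet data.

All randomness flows from a single root seed through named substreams
(`stage_seed`), so adding a stage never perturbs another stage's draws,
and a cohort is byte-identical across runs of the same configuration.

# Numerical and boundary conventions

* Usage 0/0 is missing, never 0; imputation never alters covered
  entries.
* Threshold ties resolve upward; `score > tau` is strict, so a score at
  the threshold is wild-type.
* IRLS working weights are floored at $10^{-10}$; separation is tamed by
  the ridge penalty rather than step-halving.
* Dispersion floor $10^{-8}$; Wald degeneracies (zero standard error
  with zero estimate, e.g. identical groups) report `lfc = 0, p = 1`.
* Sample odds ratios are reported as is, infinite on zero margins by
  convention.
* Probit clamp `eps = 1/(2N)` with `N` the group size.
* Fisher two-sided p-values follow the standard "sum of table
  probabilities ≤ observed" rule.

# Known limitations

* The weak-label logistic model assumes mis-splicing is the dominant
  signal separating clones; confounders correlated with donor mutation
  status (e.g. cell-type composition differences feeding into usage
  coverage) are not modeled.
* The false-positive-rate guarantee is calibration-set-based and pooled
  across wild-type donors; per-donor error rates can exceed the target
  when donors differ in baseline cryptic usage.
* Pseudobulk DE with donor fixed effects needs donors carrying both
  predicted genotypes; donors with a single group inform only the
  intercepts.
* The composition and interaction Fisher tests treat cells/pairs as
  independent; both are faithful to the source framework but
  anti-conservative under strong donor effects.
* Module scores depend on the bin/control parameters when signatures
  concentrate in few expression bins; signature genes can be drawn as
  their own controls, slightly attenuating strong effects.
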