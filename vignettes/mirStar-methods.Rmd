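---
title: "mirStar: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirStar: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirStar)
```

mirStar implements a survival-driven selection procedure for breast-cancer
subtype miRNAs and the downstream validation and regulatory-network analyses
that go with it. This vignette explains the statistical machinery, the
conventions adopted where several were defensible, the synthetic-data model
the package uses to exercise the pipeline, and the limits of what the
passing test suite demonstrates.

## The survival machinery

All estimators are built on an event table: the ordered distinct death
times $t_k$, the deaths $E_k$ at each, and the subjects $N_k$ known to be
at risk entering $t_k$. The package's censoring conventions are: an alive
patient is censored at the last follow-up day and a dead patient
contributes an event at the day of death; at a tied death/censoring time,
deaths are counted first, so a subject censored at $t_k$ is still in
$N_k$ (the standard convention).

The survival function $S(t) = P(T > t)$ is estimated with the
Kaplan-Meier product-limit estimator

$$\hat S_{KM}(t) = \prod_{k: t_k \le t} \Bigl(1 - \frac{E_k}{N_k}\Bigr),$$

and the cumulative hazard $\Lambda(t) = -\log S(t)$ with the Nelson-Aalen
estimator

$$\hat H_{NA}(t) = \sum_{k: t_k \le t} \frac{E_k}{N_k}.$$

Since $-\log(1-x) \ge x$, $-\log \hat S_{KM}$ dominates $\hat H_{NA}$
pointwise; the test suite asserts this on simulated tables.

Two groups are compared with the log-rank test. At each pooled death time
the expected deaths in group $A$ are the total deaths times $A$'s at-risk
fraction, the variance term is hypergeometric, and

$$Z = \frac{\sum_k (O_{Ak} - E_{Ak})}{\sqrt{\sum_k \mathrm{Var}(O_{Ak})}}$$

is referred to $\chi^2_1$ via $Z^2$ for a two-sided p-value. With no
events (or zero total variance) the result is flagged degenerate and
reported as $Z = 0$, $p = 1$ rather than an error, because the ranking
layer must be able to traverse hundreds of markers unattended.

The effect size is the observed/expected (Pike) hazard ratio
$\mathrm{HR} = (O_A/E_A)\,/\,(O_B/E_B)$, computed from the same
accumulations as the log-rank test. No estimator is prescribed by the
procedure this package implements alongside the log-rank test, and the
O/E estimator is the natural companion: it requires no model fit, equals
1 exactly for identical event experience, and inverts under group
exchange. Group $A$ is always the high-expression group, so
$\mathrm{HR} > 1$ means high expression carries the higher death rate.
When a group accumulates zero expected (or the denominator group zero
observed) events the ratio is undefined and reported as missing with a
warning, and the affected miRNA is excluded from that subtype's ranking
rather than imputed.

## Ranking, star sets and the $\Psi$ objective

For each tumor subtype, the subtype's patients are pooled with the
controls and every miRNA that survives the prevalence filter (at least
60% non-zero values across the analysis samples, boundary inclusive) is
median-dichotomized: values at or below the median go to the low group,
values strictly above to the high group. Sending ties low is
deterministic and stable; a marker whose values are all identical
produces a degenerate split, which is flagged and excluded. The per-miRNA,
per-subtype score is $\mathrm{HR} - p$, read literally as the difference
between the hazard ratio and the log-rank p-value.

The top $k$ (default 100, configurable) miRNAs per subtype, ranked by
descending score with lexicographic tie-breaks, are intersected:
*four-star* miRNAs appear in all four lists, *one-star* miRNAs in exactly
one. Intermediate multiplicities are reported but drive no downstream
stage. Four-star miRNAs are finally ranked by the objective

$$\Psi = \sum_{i=1}^{S} (\mathrm{HR}_i - p_i), \qquad S = 4,$$

with the $S = 1$ special case giving the one-star tables' score column.
The package ships the published reference statistics it reproduces
(`fourStarTable()`, `oneStarTable()`, printed to three decimals); note
that the reference four-star table is not strictly monotone in its
objective column, whereas `psiTable()` sorts strictly, so row orders can
differ even when every value agrees to rounding.

## Classifier validation

The selected panels are validated by stratified 5-fold cross-validation
on seven classifier families: logistic regression, decision tree, a
single-hidden-layer neural network, a linear-kernel SVM, k-nearest
neighbours, random forest, and Gaussian naive Bayes. The four-star panel
is evaluated on tumor-vs-control; each one-star panel on its
subtype-vs-rest (other subtypes *and* controls are the negatives).
Hyperparameters are the backing libraries' defaults, recorded in the
registry returned by `classifierRegistry()`, which is pluggable so exact
settings can be injected. Folds are stratified by class from a fixed
seed — plain accuracy is the only default metric, and the cross-classifier
arithmetic mean is reported alongside. Whether stratification matched the
original analysis is unknowable from the published description; it is a
package decision, chosen because the control class is small.

## Stage analysis

Tumors carry AJCC stages; sub-stages IA/IB and IIA/IIB are collapsed to I
and II and the analysis is restricted to those two stages. For four-star
miRNAs all staged tumors enter; for a one-star miRNA only its own
subtype's tumors do. Each miRNA gets a classical one-way ANOVA of
expression against stage plus a direction of change (increase when the
stage-II mean exceeds the stage-I mean). Expression enters on the
log2(rpm + 1) scale by default (`scale = "raw"` is available) — the raw
RPM scale is heavily right-skewed and the log scale is what the rest of
the pipeline analyzes. No multiplicity correction is applied by default,
matching the selection-stage convention of reporting raw log-rank
p-values; `correct = TRUE` switches on Benjamini-Hochberg. A marker with
no variance at all is reported with missing F and p rather than the 0/0
artifact a naive computation produces.

## Network refinement and circuits

Three directed relation tables — miRNA→gene targets, TF→miRNA and
TF→gene — are loaded from plain edge lists, deduplicated, and normalized
to an uppercase symbol namespace shared by genes and TFs (miRNA
identifiers keep their case, which is meaningful in miRNA nomenclature).
The eleven-step refinement alternately restricts the three sets; two
readings were possible at step 3 (whether new miRNAs may enter via the
step-2 TFs) and the contractive reading — restriction to the initial
set — is implemented, which keeps every later step a subset of an earlier
one and makes the monotonicity invariants testable. Step 9 keeps a gene
only when its mRNA profile has Pearson correlation strictly below the
threshold (default $-0.3$) with *at least one* refined miRNA, computed on
log-scale expression; the per-pair correlations are retained in a report
so the "any refined miRNA" choice is auditable. Genes without an mRNA
profile are dropped at this step with a warning.

A regulatory circuit is a pair $(m, X)$ with $m \to X$ in the miRNA
targets and $X \to m$ in the TF→miRNA table, restricted to the refined
sets; detection is by indexed lookup and is property-tested against
exhaustive triple enumeration. Networks are exported in full and
loops-only variants as GraphML and SIF. PPI edge lists are reduced to a
degree table with a configurable hub quantile. Over-representation of a
refined gene set is a plain upper-tail hypergeometric test per gene set
with BH correction; the default universe is the genes of the interaction
tables, since the original online-tool backgrounds cannot be reproduced
offline.

## The synthetic cohort model

The generator emulates the structure the analysis assumes, with a known
ground truth. Defaults (all configurable through `cohortConfig()`):

* **Cohort**: 86/39/24/41 tumors across the four subtypes plus 41
  controls (231 samples, 190 tumors), the reference sample sizes.
* **Expression**: log-normal RPM, log2-scale mean 5, sd 1; null miRNAs
  have independent expression with a 20% zero rate (so they comfortably
  pass, and occasionally fail, the 60% prevalence filter); 587 miRNAs of
  which 44 four-star and 12 per subtype one-star effect miRNAs are
  planted.
* **Latent risk**: one binary risk indicator per tumor. The high-risk
  stratum of each subtype is sized to span half of that subtype's pooled
  tumor-plus-control analysis cohort, saturating at all tumors for small
  subtypes. This choice makes the median split of a planted miRNA align
  with the risk strata instead of diluting them with controls, which is
  the property the planted effects exist to provide.
* **Survival**: exponential, baseline hazard $2\times10^{-4}$/day
  (mean ~1400 observed days of follow-up, the reference scale);
  administrative censoring at 3000 days with 30% uniform dropout;
  controls are generated with the same censoring profile since the
  analysis pools them into every subtype cohort. `effectHr` (default 3)
  is defined as the target hazard ratio between the high- and
  low-expression *halves*; where controls unavoidably spill into a small
  subtype's high arm, the latent per-patient multiplier is raised so the
  arm-level contrast still meets the target. With `effectHr = 1` the
  multiplier is exactly 1 everywhere and planted miRNAs are statistically
  indistinguishable from nulls, which the tests verify.
* **Effect sizes**: planted miRNAs shift by 3 sd (log2 scale) between
  risk strata; four-star miRNAs also sit 1.5 sd above controls in all
  tumors, one-star miRNAs 1.5 sd higher in their own subtype — large,
  deliberately clean effects that make recovery a property of the
  pipeline rather than a coin flip.
* **mRNA**: planted (miRNA, gene) pairs at target Pearson correlation
  $-0.5$; a magnitude-1 target degenerates to an exact affine transform.
* **Interactions**: each planted circuit contributes the three edges that
  make it detectable and refinable; decoy genes/TFs come from disjoint
  symbol pools so no unplanted reciprocal pair can arise, which is what
  lets exhaustive enumeration serve as the oracle.
* **Stages**: sub-stages IA/IB/IIA/IIB uniformly at random on tumors
  only; stage-shift miRNAs gain a configurable log2 shift in stage-II
  samples.

What the generator does **not** emulate: sequencing count noise and
library-size artifacts, correlated miRNA families, batch effects,
non-proportional hazards, stage-risk confounding, or any real
regulatory biology — interaction decoys are random, not drawn from real
databases. Consequently, passing recovery tests demonstrates that the
pipeline's inference machinery is correct and well-calibrated under its
own assumptions, not that the biological findings of any particular
dataset would replicate.

## Numerical and reproducibility choices

* Identical configuration + seed gives byte-identical outputs; the
  pipeline derives per-stage seeds from one global seed as
  $(97\,\mathrm{seed} + i) \bmod (2^{31}-1)$ so stages can be re-run in
  isolation.
* Ranking ties break lexicographically by miRNA id; median ties go low;
  the correlation threshold is strict (<); stage sub-stages collapse
  before testing.
* Degenerate cases (no events, zero variance, constant markers, empty
  refined sets, empty star sets) are propagated as flagged results or
  empty tables, never silent errors, so the pipeline completes on
  pathological inputs.
* Test problem sizes are chosen for desk-scale runs: the full default
  cohort (587 miRNAs, 231 samples) for recovery properties over 25
  seeds, 1000 null simulations for the log-rank type-I rate, 100 seeds
  of n = 500/arm for hazard-ratio recovery, and reduced cohorts
  (60 miRNAs) for end-to-end pipeline determinism.

## Known limitations

The score $\mathrm{HR} - p$ mixes an unbounded effect size with a
bounded probability; it is used because it is the procedure being
implemented, not because it is statistically optimal. The O/E hazard
ratio is slightly conservative (biased toward 1) under heavy censoring.
No FDR control is applied at the selection stage by design. The
refinement's step 9 depends on which mRNA profiles are supplied;
missing profiles silently shrink the refined sets (with warnings).
Classifier accuracies on synthetic data say nothing about accuracies
attainable on real cohorts.
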