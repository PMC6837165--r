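# mirStar

Survival-driven selection of breast-cancer subtype miRNAs, with
classifier validation, stage analysis, and miRNA–gene–TF regulatory
circuit detection.

## The problem

Breast cancer splits into four intrinsic (PAM50) subtypes — Luminal A
(LA), Luminal B (LB), HER2-Enriched (HER2-E) and Basal-Like (BL) — with
distinct miRNA expression profiles and distinct prognoses. mirStar is
for computational biologists who want to *select* candidate miRNAs by
their influence on patient survival within each subtype, rather than
only validating markers found by expression contrasts, and then to
interrogate how the selected miRNAs sit inside miRNA–gene–transcription
factor regulatory circuitry.

## The method

For each subtype, the subtype's tumors are pooled with the controls and
each miRNA (kept when ≥ 60% of its expression values are non-zero) is
median-dichotomized into low/high expression groups. The groups are
compared nonparametrically:

- Kaplan–Meier survival: S&#770;(t) = ∏<sub>k: t<sub>k</sub>≤t</sub> (1 − E<sub>k</sub>/N<sub>k</sub>)
- Nelson–Aalen cumulative hazard: H&#770;(t) = ∑<sub>k: t<sub>k</sub>≤t</sub> E<sub>k</sub>/N<sub>k</sub>
- log-rank test: Z = ∑(O<sub>k</sub> − E<sub>k</sub>) / √∑Var(O<sub>k</sub>), p from χ²₁ on Z²
- hazard ratio (observed/expected): HR = (O<sub>A</sub>/E<sub>A</sub>) / (O<sub>B</sub>/E<sub>B</sub>), A = high expression

Each miRNA is scored HR − p per subtype; the top k = 100 per subtype are
intersected into **four-star** miRNAs (present in all four lists) and
**one-star** miRNAs (present in exactly one). Four-star miRNAs are
ranked by the objective

Ψ = ∑<sub>i=1..4</sub> (HR<sub>i</sub> − p<sub>i</sub>).

Validation stages: stratified 5-fold cross-validation of the panels with
seven classifier families (tumor-vs-control for four-star, subtype-vs-rest
for one-star); per-miRNA one-way ANOVA of expression across AJCC stages
I/II; an eleven-step refinement of miRNA/gene/TF sets through interaction
tables with an mRNA anti-correlation filter (Pearson r < −0.3), circuit
detection (miRNA targets gene X whose TF targets the miRNA back), PPI
degree/hub summaries, and hypergeometric over-representation analysis.

A synthetic-cohort generator with a ground-truth manifest (planted
four-star/one-star effects, anti-correlated targets, planted circuits,
stage shifts) reproduces the structure of a 231-sample subtyped
miRNA-seq survival cohort so every stage is exercisable at desk scale.

## Worked example

```r
library(mirStar)

sim <- generateCohort(cohortConfig(seed = 1))
sim$cohort
#> MirnaCohort: 587 miRNAs x 231 samples
#>   subtypes: BL=41, Control=41, HER2E=24, LA=86, LB=39
#>   deaths: 149 | censored: 82
sim$truth
#> SyntheticTruth: 44 four-star miRNAs; one-star per subtype: LA=12, LB=12, HER2E=12, BL=12
#>   planted circuits: 5 | anti-correlated pairs: 10 | stage-shift miRNAs: 8

cohort <- filterMirnas(sim$cohort)          # 60% prevalence filter
subs <- c("LA", "LB", "HER2E", "BL")
lists <- lapply(subs, function(s) rankTopK(scoreSubtype(cohort, s), k = 100))
names(lists) <- subs
stars <- starClassify(lists, k = 100)
stars
#> StarSets (top-k = 100 ): 47 four-star; one-star: LA=30, LB=25, HER2E=26, BL=28

mean(sim$truth@fourStar %in% fourStar(stars))   # planted recovery
#> [1] 1
```

The 47 four-star miRNAs contain all 44 planted pan-subtype effect
miRNAs (plus 3 noise miRNAs that survived every list this seed); the
one-star lists are wider than the planted 12 per subtype because any
miRNA that enters exactly one top-100 list counts as one-star. Ranking
the four-star set by the objective:

```r
records <- do.call(rbind, lapply(subs, function(s) scoreSubtype(cohort, s)))
head(psiTable(records, fourStar(stars))[, c("mirna", "hr_LA", "p_LA", "psi")], 3)
#>          mirna hr_LA     p_LA  psi
#> 1 syn-miR-0161  3.87 1.47e-08 16.7
#> 2 syn-miR-0482  3.92 1.02e-08 14.7
#> 3 syn-miR-0093  3.67 6.73e-08 14.6
```

Each row shows a planted miRNA whose high-expression half dies at
roughly 3–4× the rate of its low-expression half (the generator's
target arm-level hazard ratio is 3) with vanishing log-rank p-values;
Ψ sums the four per-subtype (HR − p) contributions.

The whole pipeline — filtering, scoring, star sets, Ψ tables,
cross-validation, stage ANOVA, network refinement, circuits — runs from
one config:

```r
cfg <- pipelineConfig(synthetic = cohortConfig(), seed = 0)
manifest <- runPipeline(cfg, "run1")
```

or from the shell via `inst/scripts/mirstar-pipeline.R run-all`.
The package also ships the published per-subtype reference statistics
for the 44 four-star and 50 one-star miRNAs (`fourStarTable()`,
`oneStarTable()`), whose Ψ column it reproduces from the printed
(HR, p) pairs.

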