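---
title: "Selecting insect-resistance metabolites with permutation-null random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting insect-resistance metabolites with permutation-null random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trichomeRF)
library(dplyr)
```

## The problem

Wild tomato relatives store specialised metabolites in glandular leaf
trichomes: acylsugars (glucose or sucrose cores esterified with short
branched acyl chains, exuded by type-I/IV trichomes) and volatile terpenes
and methyl ketones (type-VI trichomes). Some of these compounds kill or
deter herbivorous vector insects such as whitefly and western flower
thrips, but trichome extracts are complex mixtures measured across only a
handful of accessions, so the table that links metabolites to phenotypes
is short (about 19 accessions), wide (about 160 features) and extremely
sparse — many features occur in a single accession. Ordinary
regression-based discriminant methods struggle in that regime; this
package implements a random-forest procedure with a label-permutation
null that assigns each metabolite an empirical p-value for how strongly
it separates resistant from susceptible accessions, together with the
bioassay models that define those classes in the first place.

## Phenotyping models

**Whitefly (no-choice clip cages).** Each plant carries two clip cages of
roughly fifteen adults; after five days the alive/dead counts are read.
Survival fractions are averaged cages → plant → accession
(`mean_survival()`), and a binomial GLM with logit link is fitted on
plant-level aggregated counts with accession as a fixed effect and a
sensitive standard cultivar as the intercept (`fit_whitefly_glm()`). An
accession is *resistant* when its coefficient versus the standard is
negative and Wald-significant at `alpha = 0.05`. The direction
requirement is a deliberate tightening: a significantly *higher* survival
is not resistance, and without the sign rule the most permissive
accession in a panel would be mislabelled. Accessions with 0% survival
leave the likelihood unbounded; they are excluded from the fit, flagged,
and labelled resistant directly — the biology is unambiguous. We fit
plant-level fixed effects rather than a plant random effect: with two to
three plants per accession the random-effect variance is barely
identified, and the fixed-effects fit is deterministic and reproducible.

**Thrips (leaf-disc survival).** One L1 larva per well, 24–36 wells per
accession, status read daily up to a 19-day horizon (the horizon is a
parameter, `followup_days`). `kaplan_meier()` gives product-limit curves
and median survival times; the median is the smallest observed day at
which survival reaches 0.5, on the daily grid by default. An
interpolated median (`interpolate = TRUE`) is available because daily
observation can only yield integer medians, yet half-day medians are
common in published summaries; interpolation is off by default so the
estimate never claims more resolution than the data. `fit_cox()` fits a
Cox proportional-hazards model with the accession as the explanatory
variable and Efron tie handling — on a daily grid ties are massive and
Breslow's approximation is visibly biased, though it remains available.
An accession is *resistant* when its hazard ratio versus the standard
exceeds one at `alpha = 0.01`.

## Annotation utilities

Acylsugar labels follow the `S{k}:{N}` / `G{k}:{N}` nomenclature.
Assuming saturated, non-hydroxylated acyl chains — the chains reported
for the relevant compounds (iC5, aiC5, iC11) are all of this type — the
label determines the molecular formula exactly:
C(base+N) H(baseH+2N−2k) O(baseO+k), with DBE equal to the core ring
count plus one per ester carbonyl. `formula_to_label()` inverts this by
trying both backbones and accepting only an exact CHO match, so
unsaturated or hydroxylated variants are rejected with a reason rather
than force-fitted; an exhaustive test over the grid of backbones,
k ∈ 0..6 and N ∈ 2k..40 shows the round trip is lossless and that no
formula is claimed by both backbones. Masses are monoisotopic with the
electron mass neglected (about 0.0005 u, far below the reporting
precision); the sodium adduct of S3:15 rounds to the familiar 617.

Retention indices use the van den Dool–Kratz (temperature-programmed)
linear interpolation between bracketing alkanes of a C8–C20 calibration
series, the appropriate form for a linearly ramped oven; the isothermal
logarithmic form is available behind `method = "isothermal"`. Peak areas
are normalised as `(raw / IS) × dilution / fresh weight`; because lab
conventions differ on whether a dilution factor multiplies or divides,
`dilution_action` makes the convention explicit.

`build_feature_table()` assembles replicate-level measurements into the
analysis container, summing declared co-eluting peaks (e.g. a
β-phellandrene/D-limonene pair that one cannot separate
chromatographically), zero-filling absences, and averaging replicates
into the accession-mean matrix the classifier consumes. Features enter
the forest untransformed: impurity-based tree splits are invariant to
monotone transforms, so log-scaling is reserved for display.

## The selection procedure

1. **Observed importances.** With a two-class label vector over the
   accessions, a stratified six-fold cross-validation is repeated five
   times; in each fold a 1000-tree random forest is fitted on the
   training part, its impurity (Gini) importances — normalised within
   the forest to sum to one — and its test-fold accuracy are recorded.
   Importances average folds → repeat → mean and SD over repeats;
   accuracy averages over all thirty fold evaluations. Stratification is
   a deliberate choice: with 19 samples split 8/11, unstratified folds
   can produce single-class training sets; in the rare stratified edge
   case the split is redrawn and logged.
2. **Permutation null.** The labels are permuted uniformly at random and
   the same cross-validated importance computation is re-run once per
   permuted model (a single repeat per null model — the observed run's
   five repeats reduce estimator noise where it matters, while the null
   needs many independent models more than it needs low per-model
   noise). Nulls of 100, 250 and 500 models are reported side by side;
   they are computed once at the largest size, the smaller ones being
   prefix subsets, so results are mutually consistent under one seed.
3. **Empirical p-values.** For each feature,
   `p = (1 + #{null ≥ observed}) / (1 + n_null)` — the add-one
   estimator, which cannot return zero and makes "exceeds all 100 null
   draws" correspond to p = 1/101 < 0.01. A feature is *selected* when
   its p-value at the largest null size falls below `alpha`. Both 0.01
   (stringent) and 0.05 thresholds are in circulation for this kind of
   screen; `alpha` defaults to 0.01 and the per-size p-values are all
   reported so neither convention is hidden.

Determinism: `selection_config(seed = )` fixes fold assignments, forest
seeds and permutations; each sub-computation draws its seeds from a
reproducible block so an identical call yields an identical
`rf_selection`, and the whole procedure is single-threaded by design.

## The synthetic-data generator

The generator exists so the full chain — assays in, selected metabolites
out — can be validated against a known truth. Its defaults are the
study conditions the package is built around: 19 accessions of which 8
are resistant, 80 features of which 2 are planted discriminants, six
replicates, two clip cages of 15 whiteflies on each of three plants, 30
larvae per accession observed daily for 19 days.

* **Feature tables.** Presence is decided per accession × feature:
  planted features are present with probability 0.9 in resistant and 0.1
  in susceptible accessions; background features with probability 0.15
  anywhere. Present features draw log-normal abundances
  (meanlog 10, sdlog 1 — ion-count scale spanning a few orders of
  magnitude) in every replicate, with an 8-fold abundance shift for
  planted features in resistant accessions: real discriminants differ in
  both occurrence and level, so planted effects act through both.
  Deciding presence at the accession level (rather than per replicate)
  is what makes a low background probability yield features detected in
  one accession only, the signature sparsity of real trichome profiles;
  the marginal zero probability of an entry is unchanged.
* **Whitefly assay.** Cage alive counts are Binomial(15, p) with true
  survival probabilities spread evenly from 0 (so the zero-survival
  exclusion rule is always exercised) to about 0.35 in resistant
  accessions, and from the 0.75 baseline upward to about 0.88 in
  susceptible ones — matching the 0–88% range such panels show.
  Susceptible accessions never sit below the standard (nor above its
  hazard in the thrips assay): the labelling rules are one-sided, so this
  keeps the generator's true classes consistent with what its own assays
  imply under those rules. The first susceptible accession is the
  baseline standard.
* **Thrips assay.** Death times are continuous exponentials with rate
  `baseline_daily_hazard × exp(log HR)` rounded *up* to the observation
  day, censored at the horizon. Exponential times keep closed-form
  oracles available (median day = ⌈ln 2 / rate⌉; the two-arm MLE of the
  log hazard ratio is `log((d1/T1)/(d0/T0))`); rounding-up reproduces
  the daily-grid tie structure the Cox fitter must cope with. True
  resistant log hazard ratios are spread around log 6 — hazard ratios
  well within what contrasting accessions show, where extreme pairs
  reach two orders of magnitude.

What the generator does *not* emulate: correlated metabolite families
(co-regulated biosynthesis), replicate-level batch effects, heteroscedastic
detection limits near zero, and phenotype classes that are themselves
uncertain. Passing the recovery tests therefore shows the procedure is
correct and well-calibrated under the stated statistical structure, not
that any particular real metabolite is causal.

## Numerical choices and edge cases

* Importances in a forest where no split ever occurs (all-constant
  features) are reported as all-zero, not renormalised.
* The empirical p-value is never zero; with 100 nulls the smallest
  attainable value is 1/101.
* Quasi-separated GLM coefficients (e.g. 100% survival) are flagged
  `non-estimable` via a standard-error heuristic rather than dropped;
  zero-death accessions in the Cox fit likewise.
* Clustering for display (`cluster_features()`) is complete-linkage on
  Euclidean distances of log10(x+1) abundances — the log tames the
  orders-of-magnitude spread so the dendrogram reflects co-occurrence
  rather than raw magnitude; raw and correlation distances are options.
  Features are sorted alphabetically before clustering so equal-distance
  merges resolve identically across runs.
* Standard errors of log10-scaled means in the abundance panels use the
  delta method, `se(log10 m) = se(m) / (m ln 10)`, undefined at zero
  means and reported as `NA` there.

## Problem sizes used in the test suite

The validation suite runs the full study-scale selection (19 accessions,
80 features, 5 repeats, 100-model nulls) twenty times for the recovery
and calibration checks, 500 two-arm survival replicates for
confidence-interval coverage, and reduced forests (≤ 150 trees, ≤ 60
nulls) for the behavioural unit tests — sizes chosen to estimate each
property to its Monte-Carlo precision.

## A worked run

```{r pipeline, eval = FALSE}
out <- run_pipeline(sim_config(seed = 1),
                    selection_config(n_permutations = 100, seed = 1))
glance(out$selection)
filter(tidy(out$selection), selected)
out$recovery
```

## Known limitations

With very few resistant accessions sharing a metabolite, a genuinely
bioactive but accession-exclusive compound cannot reach significance —
the permutation null cannot distinguish it from a feature tied to any
single sample. The procedure flags discriminative features, which is
association, not toxicity; direction (resistance vs susceptibility
association) must be read off the abundance panels. Impurity importances
are known to favour features with many distinct values; here all
features share the same measurement scale and sparsity regime, which
limits, but does not remove, that bias.
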