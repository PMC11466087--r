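---
title: "Classifying bacterial radiation tolerance from Pfam domain frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying bacterial radiation tolerance from Pfam domain frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radtol)
```

## The problem and the model

Experimentally measuring a bacterium's tolerance of ionizing radiation (IR)
requires culturing it, exposing it to an acute dose, and counting surviving
colonies — impossible at the scale of a metagenome. `radtol` instead predicts
the tolerance phenotype from the genome annotation alone. The quantity of
interest is the D10, the acute dose (in gray, Gy) after which 10% of exposed
cells still form viable colonies. Species are labelled **radiosensitive**
when their mean published D10 is below 200 Gy and **tolerant** otherwise; the
200 Gy cutoff sits at the bottom of the published D10 distribution, below a
wide gap in reported values, so the binary label is insensitive to modest
measurement error. A mean exactly at the cutoff is resolved to tolerant,
because the radiosensitive class is defined by "below".

The predictor space is the vector of *relative Pfam domain frequencies* of a
proteome: for each domain, the number of its instances divided by the total
number of domain instances in the genome's annotation. Instances are counted
with multiplicity — a domain occurring three times in one protein contributes
three — because the signal of interest is the relative investment of a
proteome in a family, not mere presence. Normalising by the instance total
makes the features comparable between complete genomes and partial
metagenome-assembled genomes (MAGs): subsampling an annotation changes the
numerator and denominator proportionally.

A random forest over a handful of selected predictor domains separates the
two classes. Forests suit this setting: tiny cohorts (tens of genomes),
correlated compositional features, no distributional assumptions, and an
out-of-bag mechanism that yields permutation importances without a held-out
set.

## The predictor-selection funnel

Candidate domains pass four stages:

1. **Universality** — keep domains present (count ≥ 1) in every training
   genome. A domain absent from a complete genome cannot carry a frequency
   signal, and its absence in a MAG would be uninterpretable.
2. **Abundance** — keep domains whose mean instance count per genome is
   strictly greater than 2. Frequencies of domains seen once or twice per
   proteome are dominated by annotation noise.
3. **Boruta** — the all-relevant shadow-feature race, capped at 500
   iterations. Each iteration appends a permuted ("shadow") copy of the
   candidate features, fits a forest, and scores every column by the Z score
   of its permutation importance (mean decrease in accuracy over trees
   divided by its standard deviation). A real feature scores a *hit* when it
   beats the best shadow. Hits accumulate across iterations; a two-sided
   binomial test against Binomial(n, 1/2), Bonferroni-corrected across all
   candidates, confirms features with significantly more hits than chance
   and rejects those with significantly fewer. Features undecided at the cap
   are *tentative* and treated as not selected.
4. **Stepwise pruning** — backward elimination toward the most parsimonious
   model: repeatedly estimate the cross-validated accuracy of the current
   set, tentatively drop the feature with the lowest (raw) mean decrease in
   accuracy, and accept the removal when the reduced set's accuracy is at
   least the current one's (ties favour the smaller model); stop at the
   first rejected removal.

Three Boruta design choices deserve explanation, because the algorithm's
behaviour on small, wide cohorts hinges on them.

* **Z scores, not raw importances.** Shadow columns have raw importances
  clustered at zero, so the maximum raw shadow importance is a very weak
  bar: weakly class-correlated noise clears it easily. The Z score
  normalises each feature's importance by its tree-to-tree variability; the
  maximum shadow Z score then behaves like the maximum of a few hundred
  near-standard-normal draws (≈ 3), a meaningful null quantile.
* **A constant-severity shadow pool.** The shadow pool spans the *full*
  candidate set for the whole run, including features already confirmed or
  rejected. If instead the pool shrinks as features are decided, the
  shadow-max bar collapses from "best of ~200 null features" (Z ≈ 3) to
  "best of ~10" (Z ≈ 1.6) mid-run, and features that merely happen to
  correlate with the labels in this finite cohort — with 200 background
  domains and 40 genomes the best chance correlation reaches |t| ≈ 3 —
  accumulate hits late and end up falsely confirmed. Keeping the pool full
  preserves the severity of the test from the first iteration to the last.
* **Bonferroni across all candidates, fixed.** The hit-count test is
  corrected by the number of features that entered the race, not by the
  currently undecided count. This keeps the familywise error rate of the
  whole selection fixed and, together with the iteration cap, leaves
  marginal features tentative rather than confirmed.

The stepwise stage estimates both accuracies in each comparison by
*repeated* stratified cross-validation (10 independent fold assignments by
default, the same assignments for the current and the reduced set, so the
comparison is paired). On a 40-genome cohort a single 10-fold accuracy is
quantized to steps of 0.025, and an unpaired single-assignment comparison is
close to a coin flip; pairing plus averaging makes the accept/stop decision
reflect the features rather than the folds. Ties in the lowest importance
are broken lexicographically by domain accession, making the whole funnel
deterministic given a seed.

## Training, prediction and the missing-predictor rule

`train_model()` tunes `mtry` (variables tried per split) over
`1..n_predictors` by stratified k-fold cross-validated accuracy — the same
folds for every candidate value, ties resolved toward the smallest `mtry` —
and refits the 500-tree forest on all genomes at the winner. Folds are
stratified by class because 10 unstratified folds on a cohort with ten
positives can easily produce positive-free folds.

`predict()` reports, per genome, the fraction of trees voting
radiosensitive, the predicted class (radiosensitive iff more than half the
trees vote so; exact ties go to tolerant, the majority class), and the
number of predictor domains with frequency exactly zero. A genome missing
**two or more** predictors is excluded and carries no prediction: in an
incomplete MAG a zero is indistinguishable from an assembly gap, and with
only a few predictors two zeros leave too little signal. One missing
predictor is tolerated and the genome is classified. Both the threshold and
the accounting are explicit in the report, so downstream screens can apply
stricter rules.

Permutation importance (`permutation_importance()`) is the out-of-bag mean
decrease in accuracy: per tree, the accuracy on its out-of-bag genomes minus
the accuracy after permuting one predictor's column, averaged over trees and
over independent permutations, reported in percentage points. Out-of-bag
masks come from the fitted ensemble, so no extra held-out data is needed.

## MAG incompleteness simulation

`degrade()` models an incomplete MAG by retaining exactly
`round(fraction × N)` of a genome's `N` annotation instances, drawn
uniformly without replacement from the flattened instance multiset, with
protein grouping preserved. Sampling instances (rather than unique domains
or contigs) matches how annotation mass is lost when an assembly shrinks;
per-domain retained counts are then hypergeometric. Exact-count sampling
(rather than Bernoulli thinning) realizes fixed completeness levels.
Composing two degradations at fractions f and g matches a single degradation
at f·g up to ±1 instance (nested rounding). `degradation_curve()` repeats
degrade-reclassify over a fraction grid and reports percent correct **among
non-excluded genomes** — excluded genomes are tallied separately and never
silently counted as wrong — together with the distribution of
missing-predictor counts per completeness level.

## D10 estimation from CFU assays

Surviving fractions are sham-baselined per biological replicate: the
baseline is the mean sham (0 Gy) plate count of that replicate's technical
replicates, and every dosed technical replicate contributes
`count / baseline` (values above 1 are kept — plating noise is informative).

The default dose-response model is the classical single-hit exponential,
`log10(S) = −dose/D10`, fit by least squares through the origin: zero-dose
survival is 1 by construction because fractions are already sham-scaled, and
D10 — the decimal reduction dose — is `−1/slope`. Under this model the fit
is defined even by a single positive-dose point, which is exactly the
definitional reading of D10 (a survival of 0.1 at 200 Gy *is* a D10 of
200 Gy). Zero-count plates cannot enter a log fit and are dropped with a
warning and a count (a pseudo-count alternative would bias the slope at the
doses that matter most). A positive fitted slope raises an explicit "no
dose-dependent killing" error rather than returning a negative D10. A
two-parameter logistic-in-log-dose alternative is available behind
`model = "logistic"` for shouldered curves; its D10 is where the fitted
curve crosses 0.1, and neither form claims to reproduce any particular
published fit.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces annotation cohorts with a planted, known class
signal: per genome, informative-domain frequencies are drawn from a
truncated normal around class-specific means, the remaining frequency budget
is split across background domains by a symmetric Dirichlet draw, and
integer counts are realized with a single multinomial draw of the genome's
instance total. Defaults, chosen once as the study conditions for all tests:

* **4 informative domains**, class-mean gap of 4 standard deviations
  (sd = 0.001 around base frequencies near 0.01), two enriched in each
  class so the informative frequency mass is class-balanced. Frequencies
  near 0.01 correspond to tens of instances per proteome — the
  mid-abundance regime of real predictor domains.
* **200 background domains** with Dirichlet concentration 10. The
  between-genome coefficient of variation of a background frequency is
  roughly 1/√concentration ≈ 30%, the spread one expects of conserved
  domains present in every genome. A flat Dirichlet (concentration 1) would
  instead produce dropout-prone, fat-tailed backgrounds that behave nothing
  like a universal-domain background.
* **3,000–6,000 instances per genome**, the instance total of a small
  bacterial proteome; the multinomial realization then adds counting noise
  of realistic magnitude (≈ 0.0015 at frequency 0.01) on top of the planted
  spread.
* **5 instances per synthetic protein** — protein grouping matters only to
  the parsers and the round-trip tests, not to any downstream statistic.

A ground-truth ledger records every drawn frequency and realized count, so
tests can compare any empirical statistic against the generating values, and
regeneration from the same specification is bit-identical.

What the generator deliberately does **not** emulate: phylogenetic
correlation between genomes (real cohorts are not i.i.d. — related species
share frequencies), annotation error from the upstream HMM search,
domain-domain count correlations beyond the compositional constraint, and
class imbalance in the wild. Passing tests therefore demonstrate that the
statistical machinery behaves correctly under its own assumptions — they do
not certify accuracy on real proteomes, where shared ancestry between train
and test genomes can inflate apparent performance.

`generate_survival()` draws plate counts as Poisson around the single-hit
expectation with multiplicative lognormal noise (mean 1, configurable CV),
shams included, mimicking dilution-plating variability.

## Problem sizes and numerical choices

The test-suite and acceptance-script experiments use cohorts of 20+20
genomes with the defaults above; funnel experiments run 20 independent
cohorts with 300-tree forests inside Boruta and pruning (forest quality
saturates well below that at 40 genomes and ~200 features), and survival
recovery uses 3 doses × 3 technical × 3 biological replicates at 5% CV —
the design of a typical CFU assay. Full-universe frequency rows sum to 1
within 1e-9; restricted tables keep exact zeros for absent domains rather
than missing values. All randomness flows through explicit seeds, and every
seeded routine restores the caller's RNG state.

## Known limitations

* Train/test genomes drawn from public proteomes share phylogeny; the
  synthetic cohorts here cannot expose that optimism.
* The binary label discards the orders-of-magnitude spread above 200 Gy;
  moderately and extremely tolerant species are one class by design.
* The exclusion rule counts exact zeros only; a predictor reduced to a
  single spurious instance still enters the vote.
* The log-linear survival model has no shoulder; strongly shouldered
  dose-responses should use the logistic flag or an external fit.
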