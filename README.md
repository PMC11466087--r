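# radtol

Classify bacterial genomes and metagenome-assembled genomes (MAGs) as
**tolerant of ionizing radiation** or **radiosensitive** (mean D10 below
200 Gy) from the relative frequencies of Pfam domains in their annotated
proteomes — no culturing required.

The D10 is the acute dose, in gray (Gy), at which 10% of exposed cells still
form viable colonies; under the single-hit exponential survival model,
survival at dose *d* is 10^(−*d*/D10). Published D10 values separate
cleanly into a radiosensitive tail below 200 Gy and a tolerant bulk above
it, which makes the binary phenotype learnable from genome content. The
predictor for a genome is compositional: for each Pfam domain,
`frequency = instances of the domain / total domain instances in the
proteome`, a measure that is stable under the partial annotation loss
typical of MAGs.

The package provides, as a library plus a `radtol` command-line tool:

* **Parsers** for per-protein Pfam tables and EggNOG-Mapper
  `.emapper.annotations` output, and genomes × domains frequency tables.
* **Labelling** from tables of published D10 measurements (mean per species,
  200 Gy cutoff, stratified train/test splits).
* The **predictor-selection funnel**: universality filter → abundance
  filter (mean count > 2) → Boruta shadow-feature selection (Z-score race,
  binomial hit tests, maxRuns = 500) → stepwise backward pruning by
  permutation importance under repeated cross-validation.
* A **random-forest classifier** with per-genome vote fractions and
  missing-predictor accounting: a genome lacking ≥ 2 predictor domains is
  excluded rather than guessed at.
* **MAG robustness tools**: simulate incompleteness by exact annotation
  subsampling, degradation curves of percent-correct vs completeness, and
  cohort screening summaries.
* A **D10 estimator** for CFU survival assays: sham-baselined surviving
  fractions and an origin-constrained log-linear fit (optional logistic
  alternative).
* A **synthetic-data generator** planting known class-informative domains
  against a Dirichlet-multinomial background, plus survival-assay
  simulation, so the entire workflow is testable offline.

## Worked example

```r
library(radtol)

## a 20+20 cohort with four planted informative domains
spec   <- default_cohort_spec(n_per_class = 20, seed = 7)
cohort <- generate_cohort(spec)

## frequency table restricted to the predictor domains, then train
tab   <- build_frequency_table(cohort$sets,
                               domains = c("PF90001", "PF90002",
                                           "PF90003", "PF90004"))
model <- train_model(tab, cohort$classes, seed = 11)
model
#> <radtol_model> 4 predictors (PF90001, PF90002, PF90003, PF90004), 500 trees, mtry 2, CV accuracy 0.975

head(predict(model, tab), 3)
#>   genome_id predicted_class vote_fraction n_zero_predictors excluded
#> 1     RS001  radiosensitive         1.000                 0    FALSE
#> 2     RS002  radiosensitive         0.984                 0    FALSE
#> 3     RS003  radiosensitive         1.000                 0    FALSE

## D10 from a simulated CFU assay (true D10 = 110 Gy)
assay <- generate_survival(110, doses = c(55, 110, 220), seed = 3)
fit   <- fit_d10(surviving_fraction(assay))
fit
#> <d10_fit> D10 = 105.3 Gy (loglinear model, 27 points, residual sd 0.12)
predict_survival(fit, 200)   # surviving fraction at 200 Gy: 0.0126
```

The cross-validated accuracy of 0.975 means one genome in forty was
misclassified across the stratified 10-fold splits. `vote_fraction` is the
share of the forest's 500 trees voting radiosensitive; `n_zero_predictors`
counts predictor domains absent from the annotation — at 2 or more the
genome would be reported as excluded instead of classified. The fitted D10
of 105 Gy recovers the simulated 110 Gy within the noise of a
3-dose × 3 × 3-replicate assay.

The same workflow runs from the shell:

```sh
radtol simulate --out cohort/ --seed 7
radtol train    --in cohort/ --labels cohort/labels.tsv \
                --features PF90001,PF90002,PF90003,PF90004 --out model/
radtol classify --model model/ --in cohort/ --out report.tsv
radtol fit-d10  --in assay.csv --out fit.json
```

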