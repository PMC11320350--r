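# protclock

Mortality-trained proteomic aging clocks, with competing-risks validation.

## The problem

Plasma proteomes drift with age, and that drift carries prognostic
information beyond chronological age. A *proteomic aging clock* turns a
panel of circulating protein measurements into a **proteomic age** in
years: a person whose proteome looks like that of a typical 65-year-old is
assigned a proteomic age near 65 regardless of their birth date. The
deviation (proteomic age − chronological age) is a biological-age
acceleration score that can be validated against hard outcomes — all-cause
mortality and the onset of age-related diseases — and probed biologically
through the proteins that drive it.

`protclock` implements the full construction and validation pipeline for
epidemiologists and biomarker researchers working with proteomic survival
cohorts, and ships a synthetic cohort generator with known ground truth so
every stage can be tested for parameter recovery and calibration.

## The model

Training proceeds in two stages on a participants × proteins expression
matrix with mortality follow-up:

1. **Protein selection.** An L1-penalized Cox regression of all-cause
   mortality on all proteins plus chronological age
   (`fitLassoCox()`, penalty chosen by cross-validated partial likelihood
   via `selectLambda()`).

2. **Risk-matching age transform.** Two Gompertz proportional-hazards
   models, h(t | x) = exp(β₀ + a·t + x′β), are fitted on the training rows
   (`fitGompertz()`): a *full* model on age + selected proteins, and an
   *age-only* reference. For a risk horizon k (default 10 years), the full
   model's cumulative mortality risk

   M = 1 − exp{ −e^{β₀ + x′β} (e^{ak} − 1)/a }

   is converted into the chronological age A at which the reference model
   reaches the same risk:

   A = [ log( −log(1 − M) · a₀ / (e^{a₀k} − 1) ) − β₀₀ ] / β_age

   A is the proteomic age; A − age is the acceleration score.

Validation associates the acceleration score with mortality (Cox, Efron
ties) and incident diseases under competing death (Fine–Gray
subdistribution hazards via Geskus IPCW weighting), across nested
covariate-adjustment tiers with Benjamini–Hochberg FDR; discriminative
power is compared by Harrell's C. Functional follow-up regresses the score
on each (inverse-normal-transformed) protein, maps significant proteins to
genes, and tests hallmark-style gene sets by hypergeometric
overrepresentation against a 20,260-gene background.

## Worked example

```r
library(protclock)

pc <- simulateCohort(simParams(n = 500, nProteins = 50, nCausal = 5, seed = 7))
pc
#> ProteomicCohort: 50 proteins x 500 participants
#>   deaths: 62 (12.4%)
#>   diseases: diseaseA, diseaseB
#>   missing cells: 2.10%

pc <- knnImpute(filterHighMissingness(pc, 0.5), 10L)
sp  <- splitCohort(colnames(pc), 0.7, seed = 3)
pac <- trainPAC(pc, sp$train, lambda = "cv", horizon = 10, seed = 5)
pac
#> PACModel (proteomic aging clock)
#>   horizon: 10 years; 17 selected protein(s)
#>   age-only model: shape 0.055257, age coef 0.074811

scores <- scoreCohort(pac, pc)
head(scores[, c("proteomic_age", "deviation", "risk")], 3)
cor(scores$age, scores$proteomic_age, method = "spearman")
#> [1] 0.4628843
```

The deaths fraction (12.4%) reflects the generator's calibration to ~10.9%
cumulative mortality over 13.3 years of follow-up; the Spearman
correlation between proteomic and chronological age is moderate at this
small cohort size and rises with n. Association and concordance analyses
then run on the held-out third:

```r
dev <- setNames(scores$deviation, scores$participant_id)[sp$test]
runAssociationSuite(dev, cohortData(pc)[sp$test, ], c("mortality", "diseaseA"))
compareModelsC(cohortData(pc)[sp$test, ],
               list(age = cohortData(pc)[sp$test, "age"],
                    proteomic_age = scores$proteomic_age[match(sp$test, scores$participant_id)]),
               "mortality")
```

`runPipeline(config, outDir)` chains every stage from a single config and
writes a reproducible results bundle (`scores.tsv`, `associations.tsv`,
`concordance.tsv`, `model.yaml`, `summary.yaml`, `run.log`). A thin
command-line wrapper lives at `inst/cli/protclock.R`.

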