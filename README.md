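# cafescore

Does polygenic risk for obesity show up in what people actually buy for
lunch? `cafescore` is an R package for testing associations between BMI
genetic risk scores and objectively measured workplace food purchases —
the **quality** (traffic-light healthfulness of cafeteria items), the
**quantity** (items bought over 3 months), and the **timing** (median
breakfast and lunch purchase times) — together with six self-reported
meal habits (skipping and home-preparing breakfast/lunch/dinner). It is
aimed at epidemiologists and statistical geneticists who have genotype
dosages, a GWAS weight table, point-of-sale transaction logs, and a
covariate file, and who want the whole path from raw inputs to adjusted
quartile contrasts as one tested, reproducible pipeline.

Cohorts of this kind are protected, so the package also ships a
synthetic-data generator with known generative parameters (LD-block
genotypes, a configurable BMI variance share, purchase-behavior shifts
per SD of true genetic liability). Every estimator is validated against
that ground truth and against independent oracles.

## What it computes

* **Genotype QC** — exact Hardy–Weinberg test (Levene–Haldane
  conditional distribution, two-sided), MAF / call-rate / imputation
  quality filters, sample call-rate and heterozygosity fences,
  PLINK-style method-of-moments relatedness
  (pi-hat = P(IBD=1)/2 + P(IBD=2)) with greedy pruning at pi-hat > 0.25,
  and ancestry principal components.
* **Polygenic scores** — a fixed 97-variant risk score with its
  CNS / non-CNS partition (raw = Σ β·dosage, rescaled by 2M/2Σβ to a
  risk-allele-count scale), and a genome-wide polygenic score built by
  greedy LD clumping (±250 kb, r² > 0.1) with a discovery-P threshold
  scan selecting the best fit against inverse-normalized BMI.
* **Purchase phenotypes** — Healthy Purchasing Score
  (100 × mean of green = 1 / yellow = 0.5 / red = 0 over labeled items),
  purchase counts, per-day first-purchase meal timing medians within
  06:00–10:00 / 11:00–14:00 windows, survey dichotomizations, and a
  91-day baseline window.
* **Association models** — score-quartile contrasts vs Q1 adjusted for
  age, sex, seasonality harmonics, and ancestry PCs; effects and 95% CIs
  in natural units from untransformed fits, P values from rank-based
  inverse-normal fits (logistic with Wald CIs for binary habits); trend
  tests over the quartile index; CNS vs non-CNS heterogeneity z-tests;
  Benjamini–Hochberg FDR within outcome families.

## Worked example

```r
library(cafescore)
res <- run_pipeline(default_pipeline_config(seed = 1), out_dir = "run1")
cat(readLines("run1/summary.txt"), sep = "\n")
#> cafescore run (seed 1)
#> simulated: 500 participants, 2000 variants, 61027 transactions
#> QC: 1932/2000 variants kept; 413 samples kept (87 related dropped)
#> GPS best-fit threshold 0.19 with 390 variants; PRS panel 93 variants
#> association: 48 models, 192 result rows
```

The run simulates a 500-employee cohort, applies the QC filters (68
variants fail a filter; pi-hat pruning at a 2,000-marker panel is noisy,
see the methods vignette), scans the threshold grid for the genome-wide
score, derives the purchase phenotypes from the 61,027-row transaction
log, and fits all quartile models. The highest-risk quartile of the
genome-wide score, relative to the lowest:

```r
r <- res$results
r[r$score == "BMI_GPS" & r$contrast == "Q4" &
    r$outcome %in% c("healthy_purchasing_score", "total_items",
                     "breakfast_time_median", "prepares_dinner_home"),
  c("outcome", "effect", "ci_low", "ci_high", "p", "p_trend", "p_adj")]
#>                   outcome effect ci_low ci_high     p p_trend p_adj
#>  healthy_purchasing_score -4.498 -5.715  -3.281 0.000   0.000 0.000
#>               total_items 19.858  7.066  32.651 0.002   0.006 0.006
#>     breakfast_time_median 12.684 10.446  14.923 0.000   0.000 0.000
#>      prepares_dinner_home  0.531  0.296   0.954 0.034   0.028 0.107
```

Read: under the default generative effects (−1.9 percentage points of
purchase quality, +6 items, +6 breakfast minutes, −0.45 dinner-prep
log-odds per SD of true liability), participants in the top quartile of
the estimated genome-wide score bought food that scored 4.5 percentage
points less healthy, bought ~20 more items over 3 months, purchased
breakfast ~13 minutes later, and had about half the odds of preparing
dinner at home, each relative to the bottom quartile — with effects in
natural units, P values from the inverse-normalized fits, and FDR within
the purchases/survey families. Outputs land under `run1/` (per-stage
CSVs, a JSON fit log, and a manifest with config hash and checksums);
re-running with the same config and seed reproduces identical checksums.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/cafescore.R run --out run1 [--config cfg.yaml] [--seed 1]
```

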