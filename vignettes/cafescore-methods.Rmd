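---
title: "Methods: polygenic obesity risk and workplace food-purchase phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic obesity risk and workplace food-purchase phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cafescore)
```

`cafescore` implements an end-to-end analysis of whether polygenic risk
for obesity is associated with objectively measured food-choice
behavior: the quality (traffic-light healthfulness), quantity (items per
3 months), and timing (median breakfast/lunch purchase time) of workplace
cafeteria purchases, plus six dichotomized self-reported meal habits.
Because cohort genotypes and point-of-sale records of this kind are
protected, the package ships a synthetic-data generator with known
generative parameters; every downstream stage is exercised and validated
against that ground truth.

## The analysis model

For each participant $i$ the pipeline builds four genetic exposures:

* **BMI_GPS** — a genome-wide polygenic score $S_i = \sum_j \beta_j d_{ij}$
  over clumped variants passing a discovery $P$-value threshold, where
  $d_{ij}$ is the dosage of the risk allele and $\beta_j$ the external
  GWAS weight. Greedy LD clumping retains the smallest-$P$ variant in a
  ±250 kb window and removes neighbors with in-sample $r^2 > 0.1$; the
  threshold is chosen from a grid by maximizing the $R^2$ of
  inverse-normalized BMI on the standardized score (ties to the smaller
  threshold).
* **BMI_97 / BMI_CNS / BMI_nonCNS** — fixed-panel risk scores over an
  annotated variant panel (by construction 97 variants, split 54 with
  central-nervous-system-related gene function and 43 without). Raw
  scores are rescaled by $2M / 2\sum\beta$ ($M$ = variant count, betas
  risk-oriented and non-negative) so a score reads as a weighted count of
  risk alleles in $[0, 2M]$.

Each score is split into population quartiles (Q1 = lowest risk). For a
continuous outcome $y$ the quartile model is fitted twice,

$$y \sim \mathrm{Q2} + \mathrm{Q3} + \mathrm{Q4} + \mathrm{age} +
\mathrm{sex} + \sin\theta + \cos\theta + \mathrm{PC}_{1..k},$$

once with $y$ untransformed — giving the contrast and 95% CI in natural
units (percentage points, items, minutes) — and once with $y$ replaced by
its rank-based inverse normal transform, from which the reported $P$
value is taken. This separates interpretability of the effect from
robustness of the test for skewed purchase data. Binary meal-habit
outcomes use logistic regression with Wald odds-ratio CIs. A trend test
re-enters the quartile as a single ordinal term (1–4). Stratified
CNS vs non-CNS estimates are compared with
$z = (b_1 - b_2)/\sqrt{se_1^2 + se_2^2}$, and Benjamini–Hochberg FDR is
applied to the quartile-contrast $P$ values within each outcome family
(purchases; survey behaviors). Seasonality is absorbed by one annual
harmonic pair, $\theta = 2\pi(\text{day-of-year} - 1)/365.25$.

## Genotype quality control

Variant filters (kept iff all hold): exact Hardy–Weinberg $P \ge 10^{-6}$
on hard-called genotypes, MAF $\ge 0.01$, call rate $\ge 0.98$,
imputation quality $\ge 0.50$. Sample filters: call rate $\ge 0.95$ and
heterozygosity no higher than median + 3·IQR — the fence is one-sided
because excess heterozygosity indicates contamination while low
heterozygosity in a homogeneous panel does not warrant exclusion.
Relatedness uses a method-of-moments IBD estimator: identity-by-state
counts per pair combined with their expected distribution given allele
frequencies to solve for $P(\mathrm{IBD}=0,1,2)$, and
$\hat\pi = P(\mathrm{IBD}{=}1)/2 + P(\mathrm{IBD}{=}2)$. The expected IBS
probabilities use unbiased factorial-moment estimators of the
allele-frequency products (e.g. $\widehat{p^2q^2} =
a(a{-}1)(T{-}a)(T{-}a{-}1)/T(T{-}1)(T{-}2)(T{-}3)$ for allele count $a$
of $T$ chromosomes), since frequencies come from the sample itself.
Components are clamped to $[0,1]$; pairs with $\hat\pi > 0.25$ enter a
graph from which samples are greedily dropped (highest degree first,
ties to the lexicographically smallest ID) until no edge remains, so
exactly one member of an isolated pair is removed. Ancestry is
summarized by principal components of the column-standardized dosage
matrix, with each component's sign fixed so its largest-magnitude
loading is positive.

A practical caution demonstrated by the synthetic runs: $\hat\pi$ has
per-pair sampling SD of roughly $0.017$ at 5,000 informative markers and
substantially more at smaller panels, and the $[0,1]$ clamp on the noisy
IBD components gives unrelated pairs a small positive mean. At the
desk-scale demo (2,000 markers) a few percent of truly unrelated pairs
therefore cross the 0.25 pruning threshold and some samples are lost;
genome-wide marker counts are what make this filter sharp in real
cohorts.

## Purchase phenotypes

* **Healthy Purchasing Score** = $100 \times$ mean traffic-light weight
  over labeled purchases (green = 1, yellow = 0.5, red = 0); unlabeled
  items are excluded from both numerator and denominator, and a
  participant with no labeled purchase has an undefined score.
* **Quantity** = total/food/beverage item counts over the baseline
  window; label-independent.
* **Timing** = per calendar day, the earliest food-class purchase inside
  the meal window (breakfast 06:00–10:00, lunch 11:00–14:00, bounds
  inclusive, minute resolution); the phenotype is the median of those
  daily firsts. Beverages do not qualify as a "first food" (a
  `food_only = FALSE` switch relaxes this).
* **Surveys**: skipping is dichotomized as never vs at least weekly;
  home-prepared meals as fewer than 3 vs 3+ days per week.
* **Baseline window**: 91 fixed days, half-open at enrollment
  (`enrollment - 91 <= date < enrollment`). A fixed day count keeps
  counts comparable across participants; "3 months" as calendar months
  would not.

## The synthetic cohort

`simulation_config()` fixes the generative parameters; the defaults are
the package's study conditions and are chosen to resemble a hospital
workforce cohort: 500 participants, ~81% female, age 44.9 (SD 12.8)
truncated to 20–75, BMI mean ~27.9, year-round enrollment over 18
months, and a 91-day purchase history of ~120 items at baseline color
probabilities green/yellow/red/unlabeled = 0.31/0.33/0.26/0.10.

Genotypes: 2,000 variants in 200 LD blocks. Haplotypes are built by
first-order Markov copying — each allele is copied from its left
neighbor with probability $\sqrt{r^2_{\mathrm{block}}}$, else drawn
fresh at the block frequency — so adjacent-variant genotype $r^2$
targets `block_r2` (default 0.3) and decays geometrically with distance.
Blocks sit 1 Mb apart across chromosomes 1–22, so LD never spans blocks
and clumping windows cannot cross them. A fraction `frac_causal`
(default 0.10) of variants receives causal effects
$\beta \sim N(0, \texttt{effect\_sd}^2)$ on a liability whose
standardized value is the **true score**; BMI is linear in the true
score with variance share `bmi_h2` (default 0.148) of its non-covariate
variance. The emitted weight table carries the causal betas for causal
variants, small noise weights (`effect_sd/10`) for nulls, discovery
$P \sim U(10^{-8}, \texttt{causal\_p\_max})$ for causal variants
(default upper bound 0.19, so the demo's threshold scan has signal up to
that grid point) and $U(0,1)$ for nulls, with reported allele
orientation randomized (half the rows allele-swapped and sign-flipped)
to exercise orientation resolution.

Purchase behavior shifts with the true score $Z$: item counts are
negative-binomial with mean $120 + 6Z$ (overdispersion size 8 — real
purchase counts are overdispersed, and this stresses the inverse-normal
step); colors are multinomial with the green-vs-red log-odds shifted so
the expected Healthy Purchasing Score moves by the configured
percentage points per SD of $Z$ (default −1.9, linearized at $Z = 0$);
breakfast times are normal around a mean shifted by +6 min/SD; survey
categories are drawn through logistic models (e.g. −0.45 log-odds/SD
for preparing dinner at home) so that the standard dichotomization
recovers the generative binary exactly. Timestamps fall on weekdays
within cafeteria hours (06:00–20:00). All randomness flows from the
single config seed, and identical config + seed reproduces
byte-identical files.

What the generator does **not** emulate: realistic haplotype-reference
LD (no long-range structure, equal within-block frequencies), population
substructure (ancestry PCs in the demo absorb only noise), item prices
and menus, shift work, and assortative or family structure beyond the
constructed benchmark pairs. Passing tests therefore demonstrate
correctness of the estimators under a controlled architecture, not that
real cohort estimates would be reproduced.

## Numerical and design choices

* **PRS scaling** is read as raw × $2M/2\sum\beta$; the
  "maximum-number-of-risk-alleles" interpretation pins the upper bound
  at $2M$, which only this algebra yields. Raw scores are reported
  alongside, so any other rescaling is recoverable.
* **Exact HWE** is the classical two-sided conditional test (sum of all
  heterozygote-count probabilities not exceeding the observed table's),
  evaluated by the stable recurrence from the modal count; not mid-$P$.
* **Inverse normal transform** uses offset 0.5, $z =
  \Phi^{-1}((\mathrm{rank} - 0.5)/n)$, average ranks for ties —
  symmetric and the most common variant.
* **Quartile boundaries** at type-7 empirical quantiles, right-closed
  intervals so boundary ties go to the lower quartile; a distribution
  whose cut points coincide is rejected as degenerate.
* **Clumping ties** (equal $P$) break by smaller position then
  lexicographic ID; the window is ±250 kb inclusive, 1-based positions,
  and $r^2$ is always computed in-sample (no reference panel).
* **Missing dosages** are mean-imputed as $2 \times$ effect-allele
  frequency during scoring — preserves ranking and is standard scoring
  practice.
* **Heterogeneity** between stratified estimates uses the two-estimate
  $z$ difference on the modeling scale (identity for continuous
  outcomes, log-odds for binary); the per-SD and quartile contrasts are
  tested separately.
* **Separation** in logistic fits is flagged (non-converged fit or Wald
  SE > 20) and the CI is reported as undefined rather than silently
  returned.
* **Model guards**: fits require at least 10 complete cases per
  parameter; singular designs error with the collinear columns named.

## Validation experiments and problem sizes

The test suite validates each primitive against an independent oracle
(full enumeration for exact HWE on all tables with $n \le 50$; a literal
re-reading of the greedy clumping rule on 500 random ≤20-variant
instances; a by-hand step-up for BH-FDR on all permutations of up to 6
$P$ values) and the estimators by parameter recovery:

* **Variance recovery**: 20 seeds at $n = 5{,}000$ with 600 variants in
  150 blocks (`block_r2` 0.25), `frac_causal` 0.1, `effect_sd` 0.08,
  `bmi_h2` 0.15, and causal discovery $P \le 0.01$. The last condition
  reflects a well-powered discovery GWAS — with these effect sizes a
  discovery sample in the hundreds of thousands would place causal $P$
  far below any null's — and matters mechanically: if causal variants
  carry $P$ values comparable to their null LD neighbors, the greedy
  clump sometimes retains the null and discards $1 - r^2$ of the causal
  signal, biasing the recovered variance share downward by about 0.03
  in this design. The mean incremental $R^2$ of the best-fit score on
  inverse-normalized BMI is required to lie within ±0.03 of the
  generative 0.15; per-seed sampling SD at this $n$ is ~0.009, so the
  band is assessed on the 20-seed mean. The transaction stream is
  thinned (`mean_items = 5`) in this experiment since only BMI is
  consumed.
* **Contrast recovery**: a generative Q4−Q1 quality difference of −5
  percentage points at $n = 2{,}000$ is simulated at the quartile level
  (so the estimand is exactly −5) and must be covered by the 95% CI in
  93–97 of 100 seeds.
* **Error calibration**: under null simulations ($n = 400$, skewed
  outcomes), the quartile contrast, trend, and heterogeneity tests must
  each reject at $\alpha = 0.05$ with rate 0.05 ± 0.02 over 1,000
  replicates.
* **Relatedness benchmarks**: constructed duplicate, parent-offspring,
  and unrelated pairs at 5,000 markers must land within ±0.05 of 1, 0.5,
  and 0 respectively.
* **Determinism**: two pipeline runs with identical config and seed must
  produce identical output checksums.

The demo pipeline (`run_pipeline(default_pipeline_config())`) completes
in well under a minute on one CPU at 500 participants × 2,000 variants.

## Known limitations

Scores use in-sample LD and in-sample allele frequencies, appropriate
for a single-cohort analysis but not for transferring scores across
cohorts. The relatedness stage needs genome-scale marker counts to be
sharp (see above). The generator's color-shift linearization makes the
quality effect per SD exact only near the mean of the score. At the
demo scale the genome-wide score explains less BMI variance than its
generative share because a 2,000-marker panel and ~400 analyzed
participants attenuate both tagging and the threshold scan; the
dedicated recovery experiment at $n = 5{,}000$ quantifies this properly.
Mendelian randomization and gene–environment interaction analyses are
out of scope.
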