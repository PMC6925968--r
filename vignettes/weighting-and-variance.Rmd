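---
title: "Weighting and variance estimation for complex health surveys: the svysim methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighting and variance estimation for complex health surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Health-facility surveys (Service Provision Assessment style) and household
surveys (Demographic and Health Survey style) use multi-stage stratified
designs with unequal selection probabilities: facilities are stratified by
region and facility type with hospitals oversampled to certainty, providers
and clients are subsampled within facilities under observation caps, and
enumeration areas are selected proportional to size before households are
drawn.  Analysts of such data face two recurring decisions:

1. **To weight or not to weight.** Design weights (inverse inclusion
   probabilities) remove the bias that informative sampling induces in
   unweighted means, but unequal weights inflate the variance.  The combined
   criterion is the mean squared error, MSE = bias² + variance.
2. **How to estimate standard errors.** Candidates compared here: a
   stratified cluster bootstrap (resample primary sampling units with
   replacement, carry all nested observations); single-stage design-based
   Taylor linearization with the facility as the only sampling unit
   ("svy1"); and multi-stage linearization with finite population
   corrections at every stage ("svy3").  The calibration criterion is the
   coverage probability of nominal 95% intervals in a resampling
   simulation, with average interval length breaking ties among calibrated
   methods.

`svysim` implements both studies end to end on synthetic microdata whose
design structure — and therefore whose weight algebra — is exact.

## The synthetic universe

`generate_facility_population()` creates every facility, provider and
rostered antenatal-care (ANC) client of a finite population.  Defaults
describe a scaled-down national facility census chosen once, on realism:

* 25 regions; per region **3 hospitals** (all sampled: a certainty stratum,
  emulating hospital oversampling), 30 health centers (6 sampled), 100
  dispensaries (10 sampled), 10 clinics (3 sampled).  Sampling fractions of
  0.1–0.3 in the non-certainty strata keep the finite population correction
  material, as it is in real facility censuses where the sample exceeds 5%
  of the frame.
* providers per facility by type (hospitals 3–8, dispensaries 1–3); daily
  client rosters Poisson with mean 4 per provider; observation caps of 5
  clients per provider and 15 per facility, with the "fewer than eight
  providers: interview all" rule (threshold 8).
* weights are exact inverse inclusion probabilities composed across stages:
  facility `N_h/n_h`, provider `P/p`, client `R/c` *per provider*.  The cap
  reallocation is deterministic given rosters, so client inclusion
  probabilities stay exact and Horvitz–Thompson identities hold by
  construction (they are tested by Monte Carlo over thousands of draws).
* binary indicators follow a logit model with facility-type effects,
  region effects and facility-level random effects.  The shipped scenario
  has a facility-level indicator (`ind_hb_test`, availability of
  haemoglobin testing) concentrated in hospitals — this makes the design
  informative, so unweighted client-level estimates overstate availability —
  plus two client-level indicators with moderate type effects and
  intra-facility correlation.

The household arm mirrors a DHS: enumeration areas selected by systematic
probability-proportional-to-size sampling (cumulative-total method, with
certainty extraction), a fixed number of households per EA by simple random
sampling, and all eligible women interviewed.  It differs from the real
design in one declared simplification: strata are regions only, without the
urban/rural split.

## Estimators

Point estimation uses the Hájek (ratio) mean `sum(w y) / sum(w)` — the form
survey software uses for proportions — and its unweighted counterpart;
domains are estimated by subsetting rows while keeping full-sample weights.

All design-based variances operate on Taylor-linearized scores
`u_i = w_i (y_i - yhat) / sum(w)`:

* **svy1**: per stratum *h* with PSU score totals `z_hj`,
  `V = sum_h n_h/(n_h-1) sum_j (z_hj - zbar_h)^2` — the with-replacement
  stratified formula; clustering below the PSU is ignored by design.
* **svy3**: recursively, within each group with `n` sampled of `N` units
  and unit score totals `T_j`,
  `V = (1 - f) n/(n-1) sum_j (T_j - Tbar)^2 + f sum_j V_next(j)` with
  `f = n/N`, descending stratum → facility → provider → client.  Fully
  enumerated stages (certainty hospital strata) contribute no between-unit
  variance but propagate their within-unit stages.  The same recursion with
  all `N = Inf` reproduces svy1 exactly, and on single-stage stratified
  SRS it reduces to the textbook `(1-f) s^2/n` formula — both are tested,
  as is design-unbiasedness against a brute-force two-stage enumeration.
* **cluster bootstrap**: resample facilities with replacement within
  resampling strata (matching original counts), merge their clients — each
  facility copy becomes a distinct cluster — and recompute the weighted
  mean; point estimate = mean of the B replicate estimates, SE = their
  sample standard deviation (divisor B−1), CI = empirical 0.025/0.975
  quantiles (type-7 interpolation).  Original weights are reused unchanged.

Confidence intervals for the svy methods use the t distribution with
`df = #PSUs − #strata` (the convention of design-based software; the
percentile rule for the bootstrap), clipped to [0, 1] for proportions.

## The resampling simulation

`run_simulation()` treats an observed survey as the population: truth is
the weighted estimate on the original survey, and each of R replicates
resamples units with replacement stratified by region — facilities (whose
clients are carried along) in the facility arm, women directly in the
household arm.  Resampling women ignores their household/EA clustering;
that is the procedure being emulated, and its consequence (intervals too
narrow for clustered truth) is documented rather than corrected.  Variance
methods run on the weighted estimates only.  R = 500 keeps the Monte-Carlo
standard error of a 95% coverage probability below 0.01, which motivates
the bands: good 0.93–0.97 (±2 SE), fair 0.91–0.93 or above 0.97, poor
below 0.91.

Per-replicate random-number substreams are derived deterministically from
the master seed, so runs are reproducible and replicate order is
immaterial.

### Bootstrap resampling strata inside the harness

The harness generates replicates by resampling facilities **per region**.
For the within-replicate bootstrap we therefore default the resampling
strata to the same region stratification, so the bootstrap mimics the
mechanism actually generating the data; the published procedure drew both
with the same per-region machinery.  Stratifying the bootstrap more finely
(region × type, the design strata — the default of the standalone
`cluster_bootstrap()`) is available via `bootstrap_strata_cols`, but inside
the harness it both conditions away real between-type variation and
suffers the naive n-out-of-n bootstrap's (n−1)/n variance deflation in
cells holding only 3–10 facilities; we measured ~4–6 coverage points lost
to the combination.

## Numerical choices

* **Lonely PSUs** (one sampled PSU in a stratum with more in the frame):
  the singleton's score total is centred at the grand mean of all PSU
  totals with divisor 1 (the conservative "adjust" convention).  Deeper-
  stage singleton groups — which arise only when observation caps bind —
  contribute no between-unit term; their inner stages are kept.  Certainty
  strata contribute zero at their stage by the `1 - f` factor itself.
* **Resampled replicate tables** can hold more copies of a facility than
  the stratum frame count, so sampling fractions are clipped at `f = 1`;
  a certainty stratum in a replicate then degrades gracefully to
  within-facility variance only.
* **Missing indicator values** are excluded pairwise per indicator
  (observation sections are indicator-specific); an empty domain yields a
  missing estimate, never zero.  Domains empty in some bootstrap replicate
  contribute missing values and the replicate count actually used is
  reported.
* **Quantiles** everywhere are type-7 (the interpolation default),
  documented for bit-reproducibility; CSV output uses 17 significant
  digits so round-trips are exact.
* The CIs reported for bias differences and variance/MSE log-ratios are
  percentile bootstraps over replicate indices (B_m = 1000, seeded): these
  are statistics of the full set of paired replicate estimates, for which
  no closed form is assumed.  The "% more information" comparison of CI
  lengths uses squared-length ratios (information ∝ 1/variance ∝
  1/length²); for variances the analogous quantity is the variance ratio
  itself.

## What the tests show — and what they do not

The test suite validates the machinery against independent oracles:
Horvitz–Thompson unbiasedness of weighted totals over thousands of draws
in both arms, design-unbiasedness of the multi-stage variance estimator on
an enumerable two-stage toy, hand-computed linearization examples, and
exact algebraic identities (MSE decomposition, svy3→svy1 degeneration,
census zero-variance).  The qualitative findings reproduce at reduced
scale (4 regions, R = 300, B = 100, fixed seeds, about 20 seconds of
computation): weighting removes a ~9-point bias in the
hospital-concentrated indicator at a small variance cost, and svy1
intervals are wider than svy3's on clustered indicators.

Coverage deserves a candid note.  The bootstrap's intervals are
right-sized (mean estimated SE within a few percent of the empirical
replicate SD); its true coverage sits near 0.92–0.93, mildly short of
nominal through the finite-B percentile effect.  The svy estimators,
however, stratify by region × facility type while the harness resamples
per region only — exactly as in the procedure being emulated — so the
between-type-within-region component of the generating variance is
invisible to them, and svy3's finite population corrections deflate
further against a with-replacement generating truth.  Under the synthetic
scenario's strong facility-type effects this places svy3 coverage at the
lower edge of the fair band (~0.90–0.91).  Real facility surveys with
weaker type effects need not show this; the synthetic scenario was built
to make design informativeness visible, and that same property stresses
the strata mismatch.  Passing (or narrowly missing) these bands therefore
characterises the synthetic conditions, not any real country's data.

Other declared limitations: no urban/rural stratification, default 100%
response (a stratum-level nonresponse adjustment is available but off),
no exit-interview or men's instruments, no jackknife or balanced repeated
replication, and no calibration/raking.

## Reproducing a full run

```{r, eval = FALSE}
library(svysim)
out <- run_pipeline(pipeline_config(n_regions = 4, R = 300, B = 100),
                    out_dir = "run", seed = 2015)
read.csv(file.path(out, "report_coverage_matrix.csv"))
```

The demonstration default (`pipeline_config()`: 2 regions, R = 50, B = 30)
completes in seconds; the full emulated scale (25 regions, R = 500,
B = 100) is a multi-hour single-CPU run and is not exercised by the test
suite, which uses the 4-region reduced scale throughout.
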