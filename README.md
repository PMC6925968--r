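# svysim

Simulation-based answers to two questions that recur whenever complex
survey data from health-facility or household surveys are analysed:

1. **Should rates be estimated with the design weights?** Weights (inverse
   inclusion probabilities) remove the bias that informative sampling —
   e.g. hospital oversampling — induces in unweighted means, at the price
   of extra variance. The adjudicating criterion is the mean squared
   error, `MSE = bias² + variance`.
2. **Which standard-error method should be used?** Three candidates are
   compared by coverage probability and average confidence-interval
   length: a stratified **cluster bootstrap** (resample facilities with
   replacement, carry their clients; SE = SD of B replicate estimates, CI
   = empirical 2.5/97.5 percentiles), single-stage design-based Taylor
   linearization (**svy1**, facility as the only sampling unit, strata =
   region × facility type, no finite population correction), and
   multi-stage linearization with finite population corrections at the
   facility, provider and client levels (**svy3**).

Because the real recode files of national surveys are access-restricted,
the package ships a synthetic-data module that emulates their structure
exactly: a facility universe stratified by region × type with certainty
hospital strata, provider and client subsampling under observation caps
(≤ 5 clients/provider, ≤ 15/facility, "fewer than eight providers: take
all"), and a household universe with PPS-selected enumeration areas, SRS
households and all eligible women — all with exact inverse-probability
weights, so Horvitz–Thompson identities hold by construction and every
estimator can be validated against design-based oracles.

## The core quantities

For an indicator `y` with weights `w`, the weighted (Hájek) mean is
`ŷ_w = Σ wᵢyᵢ / Σ wᵢ`. Design variances are built from linearized scores
`uᵢ = wᵢ(yᵢ − ŷ_w)/Σ wⱼ`:

* svy1: `V = Σ_h n_h/(n_h−1) Σ_j (z_hj − z̄_h)²` over PSU score totals
  `z_hj`;
* svy3, recursively per group with `n` of `N` units and unit totals `T_j`:
  `V = (1−f)·n/(n−1)·Σ(T_j−T̄)² + f·Σ_j V_next(j)`, `f = n/N`.

A resampling simulation (`run_simulation()`) treats an observed survey as
the population, draws R = 500 stratified with-replacement resamples
preserving per-region counts, and evaluates bias, variance, MSE, coverage
of nominal 95% intervals (good 0.93–0.97, fair 0.91–0.93 or > 0.97, poor
< 0.91) and average CI length.

## Worked example

A reduced-scale study — 4 regions, R = 300 simulated surveys, B = 100
bootstrap replicates, all seeded — runs in about 20 seconds:

```r
library(svysim)
pop <- generate_facility_population(facility_population_config(n_regions = 4, seed = 2015))
smp <- draw_spa_sample(pop, seed = 2016)
sim <- run_simulation(smp$clients, smp$spec, smp$indicators,
  simulation_config(R = 300, B = 100,
                    variance_methods = c("bootstrap", "svy1", "svy3"),
                    seed = 2017),
  facilities = smp$facilities)
weighting_metrics(sim, B_m = 1000, seed = 2018)
coverage_metrics(sim)
```

which prints (national rows, rounded):

```
   indicator  truth mean_unweighted mean_weighted var_ratio mse_unweighted mse_weighted
 ind_hb_test 0.3345          0.3654        0.3388    0.8303         0.0041       0.0038
 ind_wait_ok 0.7035          0.6840        0.7047    1.0601         0.0007       0.0003
 ind_weighed 0.7615          0.7863        0.7608    0.9639         0.0011       0.0005

   indicator    method coverage band avg_ci_length
 ind_hb_test      svy1    0.920 fair        0.2303
 ind_wait_ok      svy1    0.927 fair        0.0686
 ind_weighed      svy1    0.923 fair        0.0785
 ind_hb_test      svy3    0.893 poor        0.2127
 ind_wait_ok      svy3    0.907 poor        0.0646
 ind_weighed      svy3    0.907 poor        0.0732
 ind_hb_test bootstrap    0.897 poor        0.2200
 ind_wait_ok bootstrap    0.890 poor        0.0660
 ind_weighed bootstrap    0.923 fair        0.0800
```

Reading it: `ind_hb_test` is the hospital-concentrated facility indicator,
so its unweighted mean (0.365) overshoots the truth (0.335) while the
weighted mean (0.339) does not, and weighting wins on MSE; for the
client-level indicators the weighted estimator's MSE is 2–3× smaller. On
interval length, svy1 is systematically the widest (it ignores the
within-facility stages and the finite population corrections). Coverage
hovers at the lower edge of the fair band here — the estimators stratify
by region × type while the simulation resamples per region, a deliberate
property of the emulated procedure that the methods vignette discusses in
detail.

`run_pipeline(pipeline_config(), out_dir, seed)` chains
generate → draw → simulate → metrics → report under one master seed and
writes all stage CSVs, report tables (weighting comparison in the
15-column published layout, coverage matrix with band labels, CI-length
matrix with smallest/largest flags and percent-information columns) and a
JSON manifest with derived seeds and file digests.

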