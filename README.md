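# mcasym

Bilateral transcranial Doppler (TCD) asymmetry indices for predicting
functional outcome after cryptogenic stroke.

## What it does, and for whom

Cryptogenic stroke — ischemic stroke with no etiology found after full
workup — leaves clinicians without obvious prognostic markers. TCD measures
blood-flow velocity in the middle cerebral artery (MCA) through the temporal
window and yields, per side and segment, the mean flow velocity
`MV = EDV + (PSV − EDV)/3` and pulsatility index `PI = (PSV − EDV)/MV`.
`mcasym` implements, as a tested reusable pipeline for stroke researchers,
the composite **MCA index**

```
index = 100 · (MV + 10·PI) / (MV − 10·PI)        [% ; undefined if MV ≤ 10·PI]
```

its left–right **asymmetry index** `200·|R − L| / (R + L)` (percent of the
bilateral mean), and the downstream outcome analysis: group comparison
(Mann-Whitney/Welch-t, chi-square/Fisher), univariable and covariate-adjusted
logistic regression for poor 3-month outcome (modified Rankin Scale ≥ 3),
ROC analysis with Youden-optimal cutoff selection, and inter-rater ICC(A,1).
Because no patient-level registry is deposited, a seeded synthetic cohort
generator calibrated to the published group summaries makes every stage
testable end to end; see `vignette source in vignettes/mca-asymmetry.Rmd`
for the calibration and all design decisions.

## Worked example

```r
library(mcasym)

# one patient, one in-window sample per side and segment
s <- data.frame(patient_id = 1,
                side     = c("R", "R", "L", "L"),
                depth_mm = c(60, 50, 60, 50),       # M1: 58-68, M2: 44-56
                psv_cms  = c(90, 84, 75, 72),
                edv_cms  = c(45, 42, 45, 42))
p <- patient_profiles(s)
p[, c("mv_r_m1", "pi_r_m1", "idx_r_m1", "idx_r_mean", "idx_l_mean",
      "idx_asym_overall")]
#>   mv_r_m1 pi_r_m1 idx_r_m1 idx_r_mean idx_l_mean idx_asym_overall
#> 1      60    0.75 128.5714   129.7496   123.4884            4.945
```

The right M1 sample (PSV 90, EDV 45) gives MV 60 cm/s, PI 0.75, and MCA
index 100·67.5/52.5 = 128.57 %. Averaging each side's M1/M2 indices and
taking the normalised side difference gives an overall MCA asymmetry of
4.95 % — a fairly symmetric patient (the published poor-outcome group median
is ~10 %).

A full synthetic analysis:

```r
coh <- generate_cohort(cohort_params(n_total = 2000, mode = "logistic"), seed = 42)
res <- run_pipeline(coh)
res$roc
#> ROC: AUC = 0.570; Youden cutoff > 8.0241 (J = 0.139, sens 0.485, spec 0.654); 270 pos / 1730 neg
res$cutoff_fit
#> Logistic fit (n = 2000)
#>                   OR CI 2.5 CI 97.5     p
#> asym_gt_cutoff 2.310  1.699   3.141 0.000
#> male           0.516  0.373   0.713 0.000
#> age            1.058  1.044   1.072 0.000
#> nihss          1.267  1.221   1.314 0.000
#> hemoglobin     0.858  0.781   0.943 0.002
#> esr            1.021  1.016   1.026 0.000
#> d_dimer        1.001  1.000   1.002 0.001
#> time_to_tcd    1.263  1.182   1.349 0.000
```

Patients above the data-driven Youden cutoff (> 8.0 % overall MCA asymmetry)
have 2.3-fold adjusted odds of a poor 3-month outcome in this simulated
cohort, with the planted covariate effects (older age, higher NIHSS, lower
hemoglobin, ...) recovered alongside. `run_pipeline(coh, out_dir = "...")`
additionally writes `profiles.csv`, the two comparison tables, ROC points
and `models.json`.

Command line:

```sh
Rscript inst/cli/mcasym.R simulate --seed 42 --out cohort_dir
Rscript inst/cli/mcasym.R analyze --cohort cohort_dir --out results_dir
```

Both are deterministic under the seed: re-running produces byte-identical
files.

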