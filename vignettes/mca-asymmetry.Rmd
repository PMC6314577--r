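---
title: "Bilateral MCA asymmetry indices from transcranial Doppler: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilateral MCA asymmetry indices from transcranial Doppler: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcasym)
```

## The problem

In roughly a quarter of ischemic strokes no etiology is found after full
workup (cryptogenic stroke), and the short-term prognosis of these patients
is hard to anticipate. Transcranial Doppler (TCD) measures blood-flow
velocity in the basal cerebral arteries through the temporal bone window and
yields two classical parameters per vessel: the mean flow velocity (MV), a
proxy for arterial perfusion, and the pulsatility index (PI), a proxy for
distal cerebrovascular resistance. Either parameter alone discriminates
outcome weakly in cryptogenic stroke, where by definition there is no
flow-limiting stenosis. The approach implemented here combines them into a
composite per-vessel index, and then measures its *left–right asymmetry*,
the idea being that asymmetric hemodynamics — not their absolute level —
mark patients at risk of a poor 3-month functional outcome.

## The model

From each spectral-envelope measurement (peak systolic velocity PSV,
end-diastolic velocity EDV, both cm/s):

$$\mathrm{MV} = \mathrm{EDV} + \frac{\mathrm{PSV}-\mathrm{EDV}}{3},\qquad
\mathrm{PI} = \frac{\mathrm{PSV}-\mathrm{EDV}}{\mathrm{MV}}.$$

Insonation depth assigns the measurement to the proximal MCA stem
(M1, 58–68 mm) or the distal MCA (M2, 44–56 mm); the 56–58 mm gap belongs to
neither and is discarded rather than guessed (`segment_from_depth()`).

The composite **MCA index** (percent) per side and segment is

$$\mathrm{index} = 100\,\frac{\mathrm{MV} + 10\,\mathrm{PI}}
{\mathrm{MV} - 10\,\mathrm{PI}},$$

which is scale-invariant in (MV, PI), equals 100 at PI = 0, rises when MV
falls or PI rises, and is undefined when $\mathrm{MV} \le 10\,\mathrm{PI}$.
The multiplier 10 is kept as a parameter of `mca_index()` and
`index_sensitivity_grid()` lets a user verify the design property that a
larger multiplier spreads between-state differences more than a smaller one.
The per-side **mean MCA index** averages M1 and M2; the **asymmetry index**
of any bilateral quantity $Q$ is

$$\mathrm{asym}(Q) = 100\,\frac{|Q_R - Q_L|}{(Q_R + Q_L)/2}
 = 200\,\frac{|Q_R - Q_L|}{Q_R + Q_L},$$

i.e. the absolute side difference as a percent of the bilateral mean. The
**overall MCA asymmetry index** — the headline predictor — applies this to
the two per-side mean MCA indices.

*Design note (formula parse).* The printed definition of the asymmetry
index, `100 × (|Rt−Lt|) / (Rt+Lt) / 2`, is ambiguous: parsed literally
left-to-right it gives $50\,|R-L|/(R+L)$, four times smaller than the
difference-over-bilateral-mean convention the asymmetry-index literature
uses. We adopted the bilateral-mean convention because published MV
asymmetry medians of ~14–17 % at MV medians of ~55 cm/s are plausible only
under it (the literal parse would imply implausibly large absolute side
differences of >15 cm/s at the median). The literal parse remains available
via `asymmetry_index(convention = "literal")` for audit.

## From samples to profiles

`patient_profiles()` turns a long table of velocity samples into one row per
patient. Where several in-window depths exist for one side/segment, MV and
PI are combined by their arithmetic means (PI averaged directly, not
recomputed from averaged velocities — the two differ, and averaging the
ratio treats each cardiac-cycle measurement as one observation of the
resistance proxy). An undefined index ($\mathrm{MV} \le 10\,\mathrm{PI}$) is
flagged invalid and everything derived from it becomes `NA`; nothing is
imputed and nothing is silently dropped. A patient missing a side/segment
window is marked incomplete with an explicit reason, mirroring the clinical
exclusion of patients with a poor temporal window; the pipeline excludes
such patients from analysis and reports how many.

## Outcome, comparison and inference

Poor functional outcome is a modified Rankin Scale score ≥ 3 at 3 months
(`dichotomize_outcome()`, threshold inclusive); threshold 2 gives the
conservative sensitivity analysis.

Group comparisons follow clinical-paper conventions: continuous variables by
Welch *t* test when both groups pass a Shapiro–Wilk screen at α = 0.05, else
Mann-Whitney U (exact via the Wilcoxon null distribution when the combined
tie-free sample is ≤ 20, else a tie-corrected normal approximation without
continuity correction, the form SPSS reports); categorical variables by
Pearson chi-square without continuity correction, routed to Fisher's exact
test when any expected cell is below 5. The two-sided Fisher p-value is the
"small-p" sum — all tables at fixed margins no more probable than the
observed one. Quartiles use linear interpolation between order statistics
(R type 7), stated explicitly because the `median [IQR]` strings are part of
the output contract. Missing values are handled complete-case per
comparison, with missingness counted.

Outcome models are maximum-likelihood logistic regressions (IRLS) with Wald
inference; 95 % CIs are $\exp(\beta \pm 1.96\,\mathrm{SE})$ with the literal
1.96 of the stated contract (SPSS-style Wald intervals, not profile
likelihood). Constant predictors, collinear designs and (quasi-)perfect
separation are explicit, named errors — a model that cannot be estimated
should say so, not return a number. The univariable screen retains
predictors with p < 0.05 *plus sex and age always*; the fixed adjustment set
of every adjusted model is sex, age, admission NIHSS, hemoglobin, ESR,
D-dimer and time from admission to TCD (`adjustment_covariates()`).

`roc_youden()` sweeps the unique observed scores as thresholds under the
rule *score > t predicts poor* (strict inequality, matching the published
"> 9" cutoff), computes AUC by the trapezoidal rule over the full (FPR, TPR)
polygon, and picks the cutoff maximising Youden's J = sensitivity +
specificity − 1, breaking ties toward the smallest (most sensitive)
threshold; whether the original analysis used > or ≥ and its tie rule are
unstated, so both choices are documented here and fixed in code.

Inter-rater reliability uses ICC(A,1): two-way random effects, absolute
agreement, single measures — the standard form when two raters measure the
same physical quantity and systematic rater offsets should count against
agreement. The form was not stated in the source analysis; this choice is
the field default and the ANOVA mean squares are exposed in the result for
anyone wanting a different composition. The null test is
$F = \mathrm{MSR}/\mathrm{MSE}$ on $(n-1, (n-1)(k-1))$ df.

## The synthetic cohort: a stated world

No registry data are deposited, so the package ships a seeded generator
(`generate_cohort()`) whose defaults *are* the published cohort summaries —
they are calibration constants, not tuning dials:

* **Size and mix.** 377 patients, poor fraction 52/377 ≈ 13.8 %.
* **TCD marginals.** MV and PI per group/side/segment are log-normal (both
  strictly positive with right-skewed published IQRs; the true family is
  unstated) with `meanlog = log(median)` and
  `sdlog = log(q75/q25) / (2 z_{0.75})`, $z_{0.75} = 0.6745$, from the
  published group medians and quartiles.
* **Asymmetry mechanism.** The two sides of a patient share a bivariate
  normal log-scale draw with correlation ρ, *lower in the poor group* —
  asymmetry arises from decorrelation, not from a systematic side shift,
  because no side dominance is asserted by the source (its right-sided
  finding is discussed there as possibly incidental). ρ was derived once
  from the published asymmetry-index medians via the small-difference
  approximation $\mathrm{asym} \approx 100\,|\Delta\log Q|$ and
  median$|N(0,\sigma_d)| = 0.6745\,\sigma_d$ with
  $\sigma_d^2 = 2 s^2 (1-\rho)$: MV ρ = 0.72 (good) / 0.59 (poor),
  PI ρ = 0.77 / 0.71. Within a side, M1 and M2 share a patient-level effect
  (ρ = 0.7) since the analysis averages them.
* **Covariates.** Age normal, NIHSS/ESR/D-dimer/time-to-TCD rounded
  log-normal, hemoglobin normal — each matched to the published per-group
  mean ± SD or median [IQR]; risk-factor flags Bernoulli at the published
  group prevalences. mRS within the good (0–2) and poor (3–6) ranges follows
  fixed plausible multinomials (0.40/0.35/0.25 and 0.45/0.25/0.17/0.13) —
  the source publishes only the dichotomy, and only the dichotomy is
  analysed.
* **Two generation modes.** `group_first` draws the outcome, then
  group-specific distributions (for calibration checks); `logistic` draws
  everyone from the good-outcome distributions and generates the outcome
  from planted log-odds — the published univariable ORs (asymmetry 1.055/%,
  age 1.048/y, NIHSS 1.285, ...; D-dimer prints as 1.000, planted as
  exp(2·10⁻⁴) so the effect exists yet rounds to 1.000) and optionally an
  indicator effect at a threshold — with the intercept solved numerically so
  the expected poor fraction hits the target (for parameter-recovery
  checks).
* **Feasibility.** Velocity samples come from inverting (MV, PI) back to
  (PSV, EDV); PI ≥ 3 makes EDV non-positive, so such draws (≈ 6 σ events at
  the calibrated scales) are redrawn and counted. If a parameter set makes
  more than 10 % of indices undefined, the generator warns with the rate.

**What a green test does and does not establish.** The generator reproduces
the published *marginal* medians/IQRs and a decorrelation-based asymmetry
contrast; it does not reproduce the registry's joint distribution, lesion
anatomy, measurement error structure, or the exact published effect sizes
(Table-level medians such as 10.26 % vs 5.41 %, the OR 3.737, or the > 9
cutoff are sample statistics of an undeposited dataset and are *not*
asserted by any test). Green acceptance means: the formulas are exact, the
inferential machinery matches enumeration oracles, the generator hits its
own stated calibration, planted effects are recovered with nominal CI
coverage, and the file pipeline is bit-reproducible under a seed.

## Numerical choices

* Indices are carried at full double precision; percent columns are rounded
  to 2 decimals only when written by `write_profiles()`.
* Youden-tie detection uses a 1e-9 absolute band: distinct J values on a
  cohort differ by at least $1/(n_+ n_-)$, so the band only absorbs
  floating-point noise between algebraically equal expressions.
* The logistic IRLS runs with convergence tolerance 1e-10 so that the
  saturated single-binary-predictor fit reproduces the closed-form ad/bc
  odds ratio to well beyond 6 significant figures.
* Out-of-range generator draws are clamped to clinically possible supports
  (age 18–100, NIHSS 0–42, time-to-TCD 1–14 d) rather than redrawn; the
  clamp rates at the calibrated parameters are negligible.

## Known limitations

* Single-vessel, single-modality scope: no arteries other than the MCA, no
  continuous TCD monitoring, no raw spectral envelopes.
* The machine-reported vs recomputed MV question cannot be settled from the
  source; the package recomputes MV from PSV/EDV throughout (the machine
  formula is identical), so a disagreement in real data would surface as a
  data-entry issue, not be silently preferred.
* Multi-depth reduction (arithmetic means) and the ρ derivation rest on
  stated approximations; both are parameters a user can override, and the
  calibration tests only assert what the generator itself claims.
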