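# epestage

Quantitative measurement of extraprostatic extension (EPE) and
three-tier substaging of pT3a prostate cancer, in R.

## The problem

After radical prostatectomy, any tumor extension beyond the prostatic
capsule earns the single stage label pT3a, whether the protrusion is a
0.3 mm tongue or an 8 mm multifocal spread — a known source of
prognostic ambiguity for biochemical recurrence (BCR, postoperative PSA
≥ 0.1 ng/mL). `epestage` implements a quantitative alternative aimed at
pathologists and biostatisticians working with digitized prostatectomy
specimens:

* **Measurement.** From planar contours (capsule baseline polyline +
  protrusion polygons, WKT text), each EPE focus gets a radial distance
  *r* (maximum perpendicular protrusion depth beyond the capsule, mm), a
  circumferential length *w* (footprint extent along the capsule, mm),
  a 2D square area *r·w* (mm²), and a contour class (church-spire if
  *r* > 2*w*, else broad-based sessile). Missing capsule zones are
  imputed with a straight imaginary baseline; foci are counted by
  distinct source-nodule identity; multifocal cases are staged by the
  **EPE index**, the focus with the longest radial distance.
* **Substaging.** The three-tier classifier of pT3a by (*r*, number of
  foci *n*): **pT3a1** — *r* ≤ 0.75 mm, any *n*; **pT3a2** —
  0.75 < *r* ≤ 2 mm, *n* = 1; **pT3a3** — *r* > 2 mm, any *n*, or
  0.75 < *r* ≤ 2 mm with *n* ≥ 2. Plus the finer seven-group
  (radial bin × number bin) model and the circumferential-margin
  combined grouping (pT3a1+ merged with pT3a2/3−).
* **Statistics.** Cox proportional hazards (Efron ties, Wald CIs,
  Harrell's C), Kaplan–Meier/log-rank, t/chi-square demographics, and a
  C-index guided cut-off scan over candidate thresholds.
* **Simulation.** A synthetic-cohort generator calibrated to the
  published marginal structure of a 465-patient pT3a series (radial bins
  99/283/83, multifocality 49/465, 255/465 BCR events) under an
  exponential proportional-hazards model, used to validate that the
  whole pipeline recovers known hazard ratios.

## Worked example

```r
library(epestage)

cfg <- cohort_config(seed = 7)          # calibrated 465-patient cohort
coh <- generate_cohort(cfg)
staged <- stage_cohort(coh$patients)
table(staged$substage)
#> pT3a1 pT3a2 pT3a3
#>    94   252   119

fit_cox(survival::Surv(time, bcr_event) ~ substage, staged)
#> Cox proportional hazards fit (efron ties): n = 465, events = 254
#>                  HR lower upper
#> substagepT3a2 1.818 1.242 2.660
#> substagepT3a3 3.994 2.666 5.983
#> p-values: 0.0021 1.85e-11
#> Harrell's C = 0.638

km_estimate(staged$time, staged$bcr_event, staged$substage)
#> Kaplan-Meier estimate: 3 group(s), 254 event times
#> log-rank chi-square = 59.846 on 2 df, p = 1.01e-13
```

Higher tiers carry a sharply higher recurrence hazard (here ~1.8× and
~4.0× vs pT3a1) and the three curves separate decisively — the behaviour
the substaging system is designed to exhibit. A recovery experiment
confirms the pipeline is unbiased about a known truth:

```r
recover_substage_tier_hr(n_replicates = 200, seed = 7)
#> Hazard-ratio recovery over 200 replicates ( 0 failed )
#>    term true_hr   hr hr_arith sd_log_hr ci_coverage
#> 1 level   2.526 2.55    2.563       0.1       0.975
```

Geometry, from contours:

```r
base <- capsule_baseline(rbind(c(-5, 0), c(10, 0)))
rect <- rbind(c(0, 0), c(0, 1.2), c(3, 1.2), c(3, 0))
measure_focus(rect, base)   # r = 1.2 mm, w = 3 mm, area = 3.6 mm^2
classify_shape(2.5, 1.0)    # "church_spire"
count_epe_foci(c("A", "A", "B"))  # 2 (same-nodule protrusions merge)
```

## Analysis workflow

The `analysis/` scripts regenerate the full study-shaped output under
`results/`: `01_simulate_cohort.R` (cohort + geometry fixtures),
`02_measure_geometry.R`, `03_stage_cohort.R`, `04_survival_analysis.R`
(demographics, EPE-parameter Cox table, seven-group model,
uni/multivariable models, KM curves), `05_cutoff_scan.R`, and
`06_recovery.R` (hazard-ratio recovery experiments). Run them in order
from the repository root with `Rscript analysis/01_simulate_cohort.R`
etc.

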