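# rhoterm

Kinetic modelling and sequence analysis of Rho-dependent transcription
termination in bacteria.

Rho is a hexameric RNA translocase that terminates transcription at
about half of *E. coli* operons. It loads onto a C-rich, weakly
structured *rut* site on the nascent mRNA through its primary RNA
binding sites, isomerizes from an open hexamer (OH) to the closed,
translocase-competent hexamer (CH) by threading mRNA into its secondary
binding site, then translocates — hydrolysing ATP — until it catches the
elongation complex (EC) and dislodges it. A subset of terminators works
even with crippled primary RNA binding, provided the elongation factor
NusG accelerates the isomerization step; their kinetic signature is a
lag before RNA release or ATP hydrolysis starts, and a termination zone
unusually far downstream of the rut site.

`rhoterm` is aimed at people who want to reason quantitatively about
this recruitment pathway: simulate it, fit the kinds of curves the
corresponding assays produce, and benchmark the analysis logic on
synthetic data with known ground truth.

## What is in the package

* **Kinetic model** — the recruitment scheme as a linear CTMC
  `Free ⇌ Bound(OH) → Committed(CH) → step₁ … stepₙ → Released`, with
  NusG as a multiplier on the isomerization rate k₂. Mean commitment
  time in closed form,

      E[T] = (k_off + k_eff)/(k_on · k_eff) + 1/k_eff,
      k_eff = k_iso · nusg_factor  (with NusG),

  release kinetics by master-equation integration
  (`simulate_release_analytic()`), an exact stochastic sampler as
  independent oracle (`simulate_release_stochastic()`), ATP-hydrolysis
  traces (`simulate_atp_trace()`), and the catch-up model for the
  termination zone (`predict_termination_zone()`), whose mean distance

      (offset + v_RNAP·E[T]) · ρ/(ρ − v_RNAP) + v_RNAP/k_dislodge

  is inverted by `infer_commitment_time()`.
* **Kinetics fitting** — `release_fraction()` for gel-band data
  (2S/(S + (S+P))), and `fit_kinetics()`, a classic fitting front end
  returning a classed object (print/summary/coef/predict/plot/...)
  that fits exponential-rise, offset-exponential and sigmoid
  `y0 + a/(1 + (x/x0)^b)` forms, selects by AICc with a parsimony
  margin for the sigmoid, and reports a tangent-intercept lag.
* **rut scanning** — `scan_windows()` / `call_rut_sites()`: sliding
  60-nt windows scored by C/G ratio and by a self-contained
  minimum-energy folding DP (`fold_energy()`; GC −3, AU −2, GU −1
  kcal/mol, min loop 3 nt), merged into BED-style rut intervals.
* **Terminator strength** — `distance_stats()`,
  `classify_terminator()` (t_R1-like vs t_rac-like at 265 nt) and
  `terminator_strength_table()`.
* **Expression comparison** — `log2_fold_change()`, `count_affected()`
  (5-fold cutoff on the log2 scale), `overlay_classify()`
  (sbs_only / pbs_and_sbs / pbs_only / neither) and
  `ddct_fold_change()` (2^−ΔΔCt).
* **Synthetic data** — seeded generators for gel-band release
  time courses, chip-scale two-condition expression tables with planted
  effects, stem-loop sequences with planted rut windows, and qPCR Ct
  tables (`synth_config()`, `gen_*()`).

A thin command-line front end lives at `exec/rhoterm`
(`rhoterm simulate|fit|rutscan|strength|degenes|ddct|synth`).

## Worked example

Simulate the release assay for a slowly isomerizing (t_rac-like,
k_iso = 0.05/s) and a fast (t_R1-like, k_iso = 5/s) terminator, average
ten seeded replicate gel measurements, and fit:

```r
library(rhoterm)
p_slow <- rate_parameters(k_iso = 0.05)
p_fast <- rate_parameters(k_iso = 5)
ch     <- chain_spec(200)           # 200 nt from rut 3' end to the EC
times  <- c(seq(15, 180, by = 15), 240, 300, 420, 600)

avg <- function(p, nusg = FALSE) {
  ys <- sapply(100 + 1:10, function(s) {
    m <- gen_release_timecourse(p, ch, times, synth_config(seed = s),
                                nusg = nusg)
    release_fraction(m$s_half, m$s_plus_p)
  })
  timecourse(times, rowMeans(ys))
}

fit_kinetics(avg(p_slow))
#> Kinetic curve fit (16 points): selected form 'sigmoid'
#>   coefficients: y0 = 0.04885, a = 0.9577, x0 = 39.98, b = -2.705
#>   lag detected: 13.8 s (sigmoid beats exponential by AICc 7.7)

fit_kinetics(avg(p_fast))
#> Kinetic curve fit (16 points): selected form 'exp_rise_offset'
#>   coefficients: a = 1.273, b = 0.05246, y0 = -0.2775
#>   no lag detected (lag = 0 s)

fit_kinetics(avg(p_slow, nusg = TRUE))   # NusG multiplies k_iso by 100
#> Kinetic curve fit (16 points): selected form 'exp_rise_offset'
#>   no lag detected (lag = 0 s)
```

The slow terminator's release is sigmoidal with a kinetic lag — the
time needed to form translocase-competent Rho — and the lag disappears
when NusG accelerates the isomerization, reproducing the fast
terminator's exponential rise. The same contrast appears in the
termination-zone metric:

```r
zones <- data.frame(name = c("tR1_like", "trac_like"),
                    rut_end = c(120, 210),
                    zone_start = c(190, 595), zone_end = c(265, 635))
terminator_strength_table(zones, rnap_speed = 20, rho_speed = 60,
                          k_dislodge = Inf)
#>        name rut_end zone_start zone_end dist_min dist_max dist_mean     class commitment_time_s
#> 1  tR1_like     120        190      265       70      145     107.5  tR1-like          3.583333
#> 2 trac_like     210        595      635      385      425     405.0 trac-like         13.500000
```

A terminator whose zone sits 385–425 nt from the rut site implies a
~4-fold longer commitment time than a classical 70–145 nt terminator
(under the stated speeds — these are scenario parameters, not measured
constants).

See `vignettes/rho-termination-kinetics.Rmd` for the model, the fitting
and selection rules, the calibration of the rut-calling thresholds, and
what the synthetic benchmarks do and do not demonstrate.

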