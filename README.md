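# atriaflux

Quantitative analysis of intracellular Ca²⁺ handling in voltage-clamped
atrial myocytes, paired with a ground-truth simulator so that every stage of
the analysis can be validated by parameter recovery.

## The problem

Atrial contractility depends on the systolic Ca²⁺ transient, which is set by
the interplay of the L-type Ca²⁺ current (*I*<sub>Ca-L</sub>, the trigger
and loading pathway), sarcoplasmic-reticulum (SR) Ca²⁺ content and release,
SERCA-mediated reuptake, Na⁺–Ca²⁺ exchange (NCX) and plasma-membrane
Ca²⁺-ATPase (PMCA) extrusion, and cytosolic buffering. Patch-clamp plus
fluorescence recordings let all of these be quantified in one cell, but the
inference chain is long — dye calibration, exponential decay decomposition,
charge-to-moles conversion, regression slopes — and each link has
conventions and pitfalls. `atriaflux` implements the chain as tested,
auditable R functions:

- **Calibration** — Fura-2 ratiometric inversion
  *ca* = K<sub>eff</sub>(R − R<sub>min</sub>)/(R<sub>max</sub> − R), and the
  single-wavelength self-ratio form *ca* = K<sub>d</sub>R/(K<sub>d</sub>/ca<sub>rest</sub> + 1 − R)
  with R = F/F<sub>rest</sub> (K<sub>d</sub> = 1035 nmol/l by default).
- **Kinetics** — mono-exponential decay fits (A·e<sup>−kt</sup> + C);
  decomposition k<sub>SR</sub> = k<sub>sys</sub> − k<sub>caff</sub> of SR vs
  sarcolemmal removal; PMCA-only rates under NCX block; APD at any
  repolarization fraction.
- **SR flux** — SR content from the integrated caffeine-evoked NCX current
  (1 net charge per Ca²⁺; content = ∫I dt / (F·V<sub>cell</sub>), with an
  optional PMCA correction k<sub>caff</sub>/(k<sub>caff</sub> − k<sub>pmca</sub>));
  integrated L-type entry (2 charges per Ca²⁺); buffering power
  β = ΔCa<sub>total</sub>/Δ[Ca²⁺]<sub>i</sub> from the caffeine transient;
  the NCX current–Ca²⁺ slope.
- **Economy** — total transient = β·Δ[Ca²⁺]<sub>i</sub>, systolic SR release
  = total − ∫I<sub>Ca-L</sub>, fractional release = release/content,
  EC-coupling gain = release/∫I<sub>Ca-L</sub>; cell-level and
  animal-nested group summaries.
- **Simulator** — a seeded two-compartment myocyte model (free Ca²⁺ + SR
  content, linear removal pathways, fractional SR release, fixed-step RK4)
  run under the standard protocols: 0.5 Hz voltage steps (−40 mV holding,
  100 ms, +50 mV), rapid 10 mM caffeine, caffeine under Ni²⁺ NCX block,
  AP-clamp templates, nicardipine and isoprenaline conditions, with
  Gaussian noise and animal-nested cell variability.

## Worked example

Simulate a small control cohort (2 animals × 2 cells, with current and
photometric noise), run the full pipeline, and summarize:

```r
library(atriaflux)
base   <- control_preset(noise_sd_current = 2, noise_sd_fluo = 0.01)
cohort <- make_cohort(base, NULL, n_animals = 2, cells_per_animal = 2, seed = 42)
pipe   <- run_pipeline(cohort)
pipe$table[, c("cell_id", "amplitude", "k_sys", "k_caff", "sr_content", "beta", "ec_gain")]
#>           cell_id amplitude k_sys k_caff sr_content beta ec_gain
#> 1 control_cell001      89.4  8.44  0.852       65.1  545    8.16
#> 2 control_cell002      83.0  8.31  0.837       61.8  558    7.93
#> 3 control_cell003      80.1 10.91  1.175       56.4  429    7.58
#> 4 control_cell004      83.6 10.65  1.215       46.0  407    6.91
group_summary(pipe, "sr_content")
#>     group n_cells n_animals cell_mean cell_sem animal_mean animal_sem
#> 1 control       4         2     57.34     4.18       57.34      6.138
```

Each row is one cell: transient amplitude in nmol/l, decay rate constants in
s⁻¹, SR content in µmol/l of cell volume, dimensionless buffering power and
EC gain. Cells differ because the cohort generator draws animal- and
cell-level lognormal factors around the preset; every record also carries
its ground truth (`cohort[[1]]$truth_summary`), so measured values can be
checked against the generating parameters — on the standard 48-cell
validation cohort all recovery biases are below ~1.5%.

Economy arithmetic can also be used directly on published group means:

```r
economy_table(d_sys_ca = 83, beta = 565, int_ical = 0.74, sr_content = 83.9)
# total 46.9 umol/l, release 46.2 umol/l, fractional release 0.55, gain 62.4
```

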