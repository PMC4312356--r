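---
title: "Inferring cellular calcium fluxes in atrial myocytes: models and methods"
author: "atriaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cellular calcium fluxes in atrial myocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atriaflux)
```

# Overview

`atriaflux` implements the standard single-cell workflow for quantifying
intracellular Ca^2+^ handling in voltage-clamped atrial myocytes:

1. **Calibration** of fluorescence signals to free [Ca^2+^]~i~ (ratiometric
   Fura-2, or single-wavelength self-ratio anchored at rest).
2. **Kinetics**: per-beat transient amplitude, diastolic level, and
   mono-exponential decay rate constants; decomposition of removal into SR
   (SERCA) and sarcolemmal (NCX + PMCA) pathways; APD measurement.
3. **SR flux**: SR Ca^2+^ content from the integrated caffeine-evoked NCX
   current, integrated L-type Ca^2+^ entry, cytosolic buffering power and the
   NCX current–Ca^2+^ relationship.
4. **Economy**: per-cell total Ca^2+^ transient, systolic SR release,
   fractional release and excitation–contraction (EC) coupling gain.

Because no public dataset accompanies this workflow, the package ships a
**ground-truth simulator**: a two-compartment model of a voltage-clamped
atrial myocyte that generates current and fluorescence traces under the same
protocols the analysis expects. Every analysis stage is validated by
recovering the generating parameters from simulated recordings.

# The simulator

## Model

Two state variables: free cytosolic Ca^2+^ (`ca`, nmol/l) and SR Ca^2+^
content (`sr`, µmol/l of total cell volume). Cytosolic buffering is linear
with constant power $\beta$ (total/free ratio), so total-Ca fluxes divide by
$\beta$ when they move free Ca. All removal fluxes are linear in
$(ca - ca_{rest})$:

* **SERCA** uptake into the SR, free-rate constant $k_{serca}$ (s^-1^);
* **NCX** extrusion with current $i_{NCX} = -g_{NCX} C_m (ca - ca_{rest})$
  (inward-negative, one net elementary charge per extruded Ca^2+^);
* **PMCA** extrusion, free-rate constant $k_{pmca}$ (s^-1^).

The L-type current during a depolarizing step is a fast-inactivating
exponential (rate $k_{inact}$) riding on a sustained fraction $f_{sus}$ of
the peak; Ca^2+^ entry carries two charges per ion. SR release is an
instantaneous fractional dump at stimulus onset, scaled by the normalized
trigger (peak I~Ca-L~ density over a reference) *above a threshold*
$\theta$ (default 0.3):

$$ f_{eff} = f_{rel} \cdot \max\!\left(0,\ \frac{p - \theta}{1 - \theta}\right),
\qquad p = \frac{g_{CaL}}{g_{CaL}^{ref}} $$

The threshold matters. With strictly proportional scaling, blocking the
L-type current scales release and loading by the same factor and the
steady-state SR content is *invariant* to the block — contradicting the
well-established experimental observation that partial I~Ca-L~ block raises
SR content. With $\theta = 0.3$, a 30% block (nicardipine) reduces release
by ~43% while reducing loading by 30%, and the new limit cycle settles
~22% higher in SR content with a ~30% smaller transient — matching the
experimentally observed directions and magnitudes.

Caffeine application is instantaneous: the full SR content is dumped into
the cytosol and the release channels stay open, making SERCA uptake futile.
The free-Ca decay during caffeine is then exactly mono-exponential with the
closed-form rate constant

$$ k_{caff} = \frac{g_{NCX} \cdot (C_m/V) \cdot 10^9}{F\,\beta} + k_{pmca},
\qquad k_{sys} = k_{serca} + k_{caff}, $$

returned by `caffeine_decay_rate()` and `systolic_decay_rate()`; the
recovery tests target these forms. In the `caffeine_ni` protocol the NCX
coefficient is zeroed from caffeine onset (Ni^2+^ block), leaving a pure
PMCA decay.

## Integration and determinism

A fixed-step classical Runge–Kutta (RK4) scheme with a 0.1 ms step
(C++ core), sampled at 1 kHz for output. At these rates the stiffest time
constant (L-type inactivation, ~2.5 ms) is resolved ~25-fold, and the
caffeine conservation check closes to ~0.01%. Events (release dumps,
caffeine onset) are aligned to the integration grid. Non-finite states and
negative SR content abort with a diagnostic. With zero noise the output is
fully deterministic; with noise, all draws derive from the parameter set's
seed, so identical seeds give bit-identical traces.

## Presets and their calibration

`control_preset()` and `hf_preset()` are derived from measurement-level
targets — transient amplitude (83 / 60 nmol/l), buffering power (565 / 318),
SR content (83.9 / 100.1 µmol/l), decay rate constants
(k~sys~ 8.99 / 6.55 s^-1^, k~caff~ 0.745 / 0.933 s^-1^), peak I~Ca-L~
density (2.27 / 1.45 pA/pF), capacitance (59.6 / 125.9 pF) and
surface-to-volume ratio (5.06 / 4.89 pF/pl) for healthy and failing ovine
atrial myocytes. `preset_from_targets()` inverts the model's closed forms so
that these measurements *emerge* at the pacing limit cycle; at 0.5 Hz the
transient relaxes fully between beats, and the steady state satisfies
$SR^{*} = E\,k_{serca}/(f_{eff}\,k_{caff})$, with $E$ the per-beat L-type
entry (`steady_state_sr()`, `cal_entry_per_beat()`).

One consequence deserves emphasis. At a limit cycle the extruded fraction of
all removed cytosolic Ca^2+^ is exactly $k_{caff}/k_{sys}$, and extrusion
must balance entry, forcing $E = R\,k_{caff}/k_{serca}$ where $R$ is the
per-beat release. With the rate constants and amplitudes above this gives
$E \approx 4.2$ µmol/l per beat (control) — substantially more than typical
reported integrated-entry values of well under 1 µmol/l. A memoryless
linear model cannot simultaneously reproduce a caffeine-measured $k_{caff}$
and a much smaller per-beat entry; the likely biological resolution (NCX
extrudes proportionally less during a brief twitch than during a sustained
caffeine transient) is outside this model class. The presets therefore
prioritize the *measured primaries* (amplitude, $\beta$, SR content, rate
constants, peak density); per-beat entry and EC gain take their
flux-balance values, and the sustained I~Ca-L~ fraction is correspondingly
large ($f_{sus} \approx 0.70$ control, $0.85$ HF). Parameter-recovery tests
always compare measurements against each simulated cell's own ground truth,
so this choice does not weaken them.

Similarly, a single linear extrusion model cannot hold a PMCA-only rate
constant (reported near 1.2 s^-1^ when NCX is blocked) *inside* a total
sarcolemmal rate constant of 0.745 s^-1^. The presets assign PMCA a 15%
share of $k_{caff}$ ($k_{pmca} \approx 0.11$ s^-1^ control), consistent
with the observation that even a 50% change in PMCA activity alters the
NCX-derived SR content estimate by less than 10%. The Ni^2+^ protocol on
synthetic cells recovers this generative value, not the larger published
one; both are reported by the pipeline without forcing consistency.

## Cohorts, variability and noise

`make_cohort()` emulates the *n* cells from *N* animals design: a
mean-preserving lognormal factor per animal (default CV 10%) times one per
cell (default CV 5%) multiplies the biological parameters (peak density,
SERCA rate, NCX coefficient, PMCA rate, release fraction, buffering power,
resting Ca^2+^, capacitance). The surface-to-volume ratio is held fixed, as
observed experimentally, and each cell starts on its own analytic limit
cycle. Measurement noise is additive, Gaussian and independent per sample:
2 pA on each current channel and 1% of resting fluorescence on the optical
channels in the validation cohorts — typical magnitudes for whole-cell
recordings and photometry at these gains. Noise levels, CVs and seeds are
part of the generator configuration, fixed once.

What the generator does *not* emulate: subsarcolemmal Ca^2+^ gradients and
t-tubule geometry, stochastic channel gating, bi-exponential or
load-dependent decays, saturable buffering (a constant $\beta$ is assumed
because the analysis itself fits straight buffering lines), spontaneous
release events, drift, bleaching or motion artifacts. Passing recovery
tests on these synthetic cohorts therefore demonstrates correctness of the
*estimators* under the stated statistical structure, not robustness to
every pathology of real recordings.

# Analysis choices

## Calibration

The self-ratio form inverts $F = F_{max}\,ca/(ca + K_d)$ anchored at rest:
with $R = F/F_{rest}$,
$ca = K_d R / (K_d/ca_{rest} + 1 - R)$, so $R = 1$ maps exactly to the
resting anchor and saturated samples (denominator $\le 0$) are errors or,
in pipeline use, masked and flagged; downstream fits ignore masked samples.
$K_d$ defaults to 1035 nmol/l (Fluo-5F at physiological conditions). The
resting anchor is taken per cell from the resting Fura-2 ratio when a
ratiometric channel exists, mirroring the dual-dye practice of anchoring
single-wavelength dyes on ratiometric resting measurements; the Fura
constants (R~min~ 0.30, R~max~ 3.00, K~eff~ 1100 nmol/l) are plausible
in-vitro defaults — instrument calibrations, not published values — and are
user-configurable.

## Decay fits and windows

Removal is quantified by least-squares mono-exponential fits
($A e^{-kt} + C$, Levenberg–Marquardt with log-linear initialization).
Bi-exponential fits are deliberately out of scope. The systolic fit window
runs from where the transient has fallen to 90% of its amplitude down to
10%, but never starts before the end of the depolarizing step: during the
step, ongoing L-type entry distorts the removal estimate by up to ~10%.
Both fractions and the deferral are configurable. Fits with $k \le 0$, poor
convergence, or RMSE above 10% of amplitude are flagged, never silently
dropped or clamped; the SR/sarcolemmal decomposition
$k_{SR} = k_{sys} - k_{caff}$ is exact arithmetic with sign flags.

## SR content and the integration window

The caffeine-evoked inward current deflection below the pre-caffeine
baseline (median over 2 s) is integrated over the **full** post-caffeine
window rather than truncated where the current re-enters the noise band: a
2-SD truncation discards the exponential tail *below* the threshold and
biases the content low by 5–7% at realistic noise, whereas zero-mean noise
integrated over the window only adds variance. The return-to-baseline
criterion (smoothed current within 2 SD) is retained as a *flag* for
incomplete decays, alongside a minimum signal-to-noise flag. The PMCA
correction multiplies the NCX-derived content by
$k_{caff}/(k_{caff} - k_{pmca})$ when an NCX-blocked decay is available,
or by $1/(1 - s)$ for a configured share $s$; in the linear model this
correction is exact, and the conservation test holds it to <2%.

## Buffering power and NCX slope

During the caffeine decay the SR is empty, so cytosolic total Ca^2+^
remaining at time $t$ equals the corrected extrusion integral from $t$ to
the end. Regressing that total (µmol/l) on simultaneous free Ca^2+^
(converted to µmol/l) gives $\beta$ as a dimensionless slope — exactly the
$\Delta$total/$\Delta$free definition, with no +1 adjustment for the free
ion itself. The regression uses the central 80% of the free-Ca^2+^ range
(10% trimmed at each end) to avoid release and plateau artifacts, requires
at least 10 points, and flags $r^2$ below 0.9. The NCX–Ca^2+^ relationship
is an ordinary least-squares fit of inward NCX current density on free
Ca^2+^ over the same decay, returning the coefficient in pA/pF per nmol/l.

## Economy and group summaries

Per cell: total transient $= \beta \cdot \Delta[Ca]_i$ (nmol→µmol),
systolic SR release $=$ total $-$ integrated entry, fractional release
$=$ release / SR content, EC gain $=$ release / entry. These identities are
enforced exactly. An alternative bookkeeping — the post-release SR content,
SR content $-$ release — is exposed as `sr_content_post_release`, since the
caption-style formula "content $-$ (total $-$ entry)" describes that
quantity rather than the release itself. Values outside physical ranges
(fractional release outside [0, 1], entry exceeding the total) are flagged,
not clipped. Group summaries are reported both at cell level
(mean ± SEM over cells) and animal-nested (mean of per-animal means), with
an optional log10 transform; full mixed-effects modelling is deliberately
left to dedicated statistical software — `results_table()` exports a tidy
per-cell table with `animal_id` for exactly that purpose.

## APD

Action-potential duration is measured from the maximum-upstroke-velocity
point to the first crossing of peak $-$ fraction × (peak $-$ baseline),
with linear interpolation; the baseline is the mean pre-upstroke potential.
The reference point is a package choice (conventions differ between
laboratories) and the measurement is template-validated to ±1 ms.
`make_ap_template()` provides a geometric command waveform for AP-clamp
protocols; no mechanistic atrial AP model is attempted, so AP-clamp
waveforms are user-supplied templates.

# Validation problem sizes

The shipped validation suite uses: a 6+6-animal × 4-cell noisy cohort
(48 cells, three protocols each) for parameter recovery — biases are below
~1.5% for every recovered quantity, against a 5% acceptance bound; single
noiseless preset cells for conservation (≤0.01%), closed-form decay rates,
and control-vs-disease contrast signs; 80-beat runs for limit-cycle
convergence (the per-beat contraction factor is
$1 - f_{eff} k_{caff}/k_{sys} \approx 0.954$ for the control preset, so a
20% SR perturbation decays below 0.5% within 80 beats); and 1000-point
grids for calibration round trips (exact to double precision). The
`scripts/acceptance.R` entry point re-derives all headline quantities from
scratch under a caller-supplied seed.

# Known limitations

* The model is spatially homogeneous and linear; it cannot represent
  simultaneously a caffeine-conditioned $k_{caff}$ and a much smaller
  per-beat flux balance, nor a PMCA rate exceeding the total sarcolemmal
  rate (see above). Both discrepancies are documented rather than hidden.
* The isoprenaline condition scales the L-type peak and SERCA rate only;
  its emergent SR-content and amplitude responses are directionally correct
  but exaggerated relative to real β-adrenergic responses, which engage
  additional targets (phospholamban, troponin, I~Kr~/I~Ks~).
* Calibration assumes no bleaching, background drift or motion; the trace
  schema carries no correction channels.
* Saturable buffering exists in real cells; the linear-$\beta$ assumption
  matches the analysis convention, and both simulator and fits share it, so
  recovery tests cannot detect its violation.
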