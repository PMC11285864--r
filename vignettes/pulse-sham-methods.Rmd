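---
title: "Designing and analysing sham-controlled magnetic-pulse experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing sham-controlled magnetic-pulse experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsesham)
```

## The problem this package addresses

A candidate magnetoreceptor in migratory birds is built from single-domain
magnetite: nanoscale particles whose magnetization flips once an external
field exceeds their switching field. Pulse experiments exploit this — a
millisecond-scale field of tens of mT should remagnetize the particles and
corrupt the map information they supply, while leaving other senses intact.
The confound is electromagnetic induction: any pulsed field induces an
electric field proportional to −dB/dt, strong enough (transcranial magnetic
stimulation works this way) that neural side effects cannot be excluded. A
behavioural response to a pulse therefore only implicates the particle
sensor if the experiment includes a sham exposing birds to the *same*
induced electric field without a remagnetizing peak.

`pulsesham` implements that design logic as software: a circuit-level pulse
simulator, a sham designer and verifier, a device audit, the five-trait
behavioural battery, and a synthetic cohort generator that lets all of the
statistical machinery be calibrated without field data.

## The circuit model

The pulser is a charged capacitor bank discharging through the pulse coil.
With the switch closed at $t = 0$,

$$L \ddot I + R \dot I + I/C = 0, \qquad I(0) = 0,\ \dot I(0) = U_0/L,$$

whose closed form is sampled directly (no numerical integration). The
damping regime is chosen by comparing $\alpha = R/2L$ with
$\omega_0 = 1/\sqrt{LC}$; when $|\alpha - \omega_0| < 10^{-9}\,\omega_0$
the critically damped form $t\,e^{-\alpha t}$ is used, because the over-
and underdamped expressions suffer catastrophic cancellation there. The
test suite checks all three regimes against an independent `deSolve`
integration to a relative error of $10^{-6}$.

Key consequences the package leans on:

* the onset slope is $U_0/L$ regardless of $R$ and $C$ — for the 230 V /
  170 mH coil, 1.353 A ms⁻¹, i.e. 32.5 mT ms⁻¹ at 24 mT A⁻¹ — so truncating
  the pulse early changes the peak without changing the onset spike;
* the field at a fixed position is proportional to the current
  ($B = kI$), so one conversion factor carries the field trace;
* capacitor energy $\tfrac12 C U_0^2$ strictly bounds peak coil energy
  $\tfrac12 L I_{peak}^2$ whenever $R > 0$ (an invariant test).

Two shut-off models cover the two device generations: a linear current ramp
(a hard switch; the descent is not described at circuit level, so a
configurable fall time — 0.69 ms treatment, 0.1 ms sham by default — stands
in for the snubbed transient) and a flyback-diode exponential with
$\tau = L/R$, truncated at $10^{-4}$ of the peak. The capacitor charging
path is not simulated: pulses start from a fully charged bank. The switch
on-resistance (0.024 Ω) is accepted in configuration but folded into the
~80 Ω coil resistance that dominates the loop. No spatial field profile,
semiconductor transients or thermal effects are modelled.

The default grid step is 1 µs, which resolves even a 0.1 ms sham pulse with
100 samples; `solve_discharge()` refuses steps coarser than $t_d/50$.

Model against measurement: the ideal circuit predicts 2.657 A at 7.9 ms for
the 2021 bank and 2.404 A at 5.7 ms for the 2020 bank, matching the
measured 2.65/2.4 A; but it predicts 0.26 A at 0.2 ms where 0.24 A was
measured, and $k I_{peak} = 63.8$ mT where 52 mT was measured — consistent
with unmodelled series resistance and geometry. For this reason
`pulse_metrics()` lets measured quantities flow through the same adequacy
verifier as modelled ones, with provenance recorded in the report.

## Sham design and verification

`design_sham_duration()` exploits the strict monotonicity of $I(t)$ before
the peak: the smallest $t$ with $I(t) = \rho \cdot I_{peak}$ is found by
`uniroot` on the closed form, guaranteeing the simulated peak ratio matches
the target to $10^{-6}$. For the 2020 circuit and $\rho = 0.1$ this yields
0.186 ms; the physical device used 0.2 ms.

`verify_sham_adequacy()` evaluates four criteria: onset-rate match within a
relative tolerance (default 1 %), peak ratio at most 10 %, sham peak below
the 12 mT no-effect threshold, treatment peak at or above the 25 mT
full-switch threshold. Design choices here:

* **Thresholds are inclusive on the stronger-effect side** (≥ 25 mT is a
  full switch, < 12 mT is sub-threshold); the boundary behaviour is a
  convention, stated rather than derived.
* **The 12/25 mT defaults and the 10 % bound are configurable**: they stem
  from the magnetization curves of a single characterised receptor
  candidate (in trout) and from a design argument about coercivity
  spectra, not from songbird data.
* **Onset rates are compared over the first 5 % of the shorter (sham)
  on-phase.** A sham is a strict prefix of its treatment pulse, so fitted
  over a common window the ideal mismatch is zero and the tolerance
  absorbs only sampling error. `waveform_metrics(onset_window=)` exists
  for exactly this.

The device audit applies the same operational definition to previously
published pulsers from their measured numbers only: a control mode is an
adequate electric-field control only if its onset dB/dt matches the
treatment's. A double-wrapped solenoid whose control mode leaks ~1 % of the
treatment field fails; a truncation sham passes by construction.

## The statistical battery

The five traits are compared sham vs treatment in each year × age subset
and in the pooled ones (nine columns, laid out as the standard 5 × 9 grid):

| trait | test |
|---|---|
| first-night departure | Pearson χ² with continuity correction |
| stopover duration | Wilcoxon rank sum |
| departure timing (night fraction) | Wilcoxon rank sum |
| departure bearing | Mardia–Watson–Wheeler |
| flight-direction consistency | Mardia–Watson–Wheeler |

Missing traits are dropped test by test (pairwise deletion), so sample
sizes decline across traits exactly as they do in telemetry data, and no
multiple-testing correction is applied — the grid reports raw p-values, as
the battery's users expect to read them.

**Wilcoxon exactness.** Ties block the classical exact distribution, so the
package computes the permutation distribution of the midrank sum directly:
midranks are doubled to integers and a compiled counting recursion
enumerates all $\binom{N}{n_x}$ subset sums. The `auto` policy uses this
exact route for pooled sizes up to 30, or up to 100 when ties are present;
beyond that the tie-corrected normal approximation with continuity
correction takes over. The cap is a tractability decision: the recursion's
cost grows with $N \cdot \min(n_x,n_y) \cdot N(N+1)$, and at the cohort
sizes used for calibration (N = 120) the normal approximation is accurate
to well under the granularity any decision depends on. Exactness is
verified against brute-force enumeration of all labelings for every pooled
size up to 10, ties included.

**Circular tests.** The Rayleigh test uses the standard series
approximation for the p-value of $Z = n r^2$. The Mardia–Watson–Wheeler
statistic follows the classical uniform-scores definition
$W = 2\left[(C_1^2+S_1^2)/n_1 + (C_2^2+S_2^2)/n_2\right]$ with scores
$\beta_j = 2\pi\,\mathrm{rank}_j/N$, referred to $\chi^2_2$. Ranks are
undefined under ties, and bearings rounded to 1° tie frequently; tied
observations are therefore randomly ordered, the test repeated (10 000
times by default for a single analysis), and the median statistic and
p-value reported. A permutation p-value (random relabelings within each
evaluation) is exposed as an alternative to the $\chi^2_2$ approximation.
At very small samples the $\chi^2_2$ approximation is crude: against the
exhaustive 70-assignment permutation distribution at $n_1 = n_2 = 4$ it
deviates by up to ~0.08 where the permutation p is below 0.3, and by up to
~0.2 in the middle of the distribution, which is why the function warns
below 10 angles per group.

**Degenerate inputs.** A subset with an empty group, a zero table margin or
too few angles yields an `NA` grid cell rather than an error; two constant
equal-mean samples give t = 0, p = 1 by convention.

## The synthetic cohort generator

The generator emulates the structure of a two-year, two-age-class,
two-group field cohort, with one parameter row per cell:

* first-night departure is Bernoulli (defaults 0.57 juveniles, 0.44
  adults); birds that stay draw $1 + \mathrm{Geom}$ stopover nights
  (tail means 3 and 8 nights) — reproducing the zero-median, long-tailed
  stopover distributions seen in the field (juvenile quartiles 0–1,
  adult 0–9, ranges into the twenties);
* departure timing is Beta(2, 5), median ≈ 0.25 of the night;
* bearings are von Mises (means 110°/130°, κ = 1, resultant length
  ≈ 0.45, inside the 0.35–0.87 range of field resultant lengths), drawn
  with the Best–Fisher rejection sampler;
* consistency deviations are von Mises around −13° with κ = 3
  (r ≈ 0.8), and the coast bearing is reconstructed as departure plus
  deviation;
* ties arise from rounding (bearings to 1°, fractions to 0.01) rather
  than from discrete sampling, mirroring how real measurements acquire
  them.

Traits are generated independently within a bird; any true dependence
between timing and direction in real birds is not represented. Nor are
weather, detection probability, or within-season trends. Passing
calibration on these cohorts therefore shows the tests hold their level
under realistic marginal distributions, ties and sample sizes — not that
the generator is a faithful joint model of robin behaviour.

All randomness flows from one user-visible seed through a deterministic
child-seed mixer (`child_seed()`), so the repeated-MWW loop, each battery
cell and each Monte-Carlo repetition can be re-run independently.

## Calibration and power

`monte_carlo_power()` generates cohorts under a null and an effect
configuration, runs the battery on the pooled column, and reports rejection
rates with Wilson intervals. Two scaling choices are deliberate: the power
loop runs the MWW tie-break median over 200 repetitions rather than 10 000
(the median is stable long before that, and the loop multiplies the cost),
and the exactness policy can be relaxed to the normal approximation, which
at the loop's sample sizes is indistinguishable in level.

The acceptance suite calibrates the battery under the null generator with
60 birds per group in one year × age cell and 2000 repetitions at
$\alpha = 0.05$. A nominal-level band of [0.03, 0.07] is the acceptance
window. For the departure-probability trait the size is not estimated by
simulation at all: it is computed exactly by summing binomial
probabilities over every possible pair of departure counts (the
Monte-Carlo run is only required to agree with that exact value within
its own sampling error). The exact size, ≈ 0.034, is a reminder that the
continuity correction is conservative; the rank and circular tests, which
have no closed-form null size, sit near 0.05 in the simulation.

## Known limitations

* The circuit model is ideal (no ESR beyond the coil, no semiconductor
  drops); measured peaks run ~10–20 % below it, hence the
  measured/modelled provenance flag rather than a corrected model.
* The MWW $\chi^2_2$ p-value is asymptotic; below ~10 angles per group,
  use the permutation option.
* The generator's independence assumptions above.
* Night boundaries, fuel-load formulas and the classification of raw
  radio detections into trait records are upstream of this package:
  ingestion starts at the per-bird record.
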