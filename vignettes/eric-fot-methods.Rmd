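---
title: "Respiratory impedance analysis with the extended RIC model: methods"
author: "ericfot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory impedance analysis with the extended RIC model: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ericfot)
```

## The measurement and the model

The forced oscillation technique (FOT) superimposes small pressure
oscillations (about 1 cmH2O peak) on quiet tidal breathing and measures the
resulting flow at the mouth. Because the perturbation is small, the
respiratory system responds approximately linearly, and its mechanical state
is summarized by the complex respiratory impedance

$$Z_{rs}(f) = \frac{\bar G_{PV}(f)}{\bar G_{VV}(f)},$$

the ratio of the averaged pressure-flow cross-spectrum to the averaged flow
auto-spectrum. The real part of $Z_{rs}$ is the resistance, the imaginary
part the reactance. The excitation used here (and emulated by the
generator) is a pseudorandom multisine covering 2-32 Hz in 2-Hz steps.

`ericfot` implements the full analysis chain around this quantity:

1. **Spectral estimation** of $Z_{rs}$ and of the squared coherence
   $\gamma^2$ from pressure/flow records, with a coherence quality gate and
   averaging of repeated exams.
2. **Oscillometry indices**: R0 and S (intercept and slope of resistance
   over 4-16 Hz), R4, the resonant frequency fr, the mean reactance Xm, the
   reactance area Ax, the dynamic compliance
   $C_{dyn} = -1/(2\pi f X_{4Hz})$, and the 4 Hz impedance modulus Zrs4.
3. **Equivalent-circuit fitting** of the extended RIC (eRIC) model,

$$Z(f) = R + j\,2\pi f I + \frac{R_p}{1 + j\,2\pi f R_p C},$$

   where $R$ is central airway resistance, $R_p$ peripheral (small-airway)
   resistance, $I$ inertance and $C$ alveolar compliance; the total
   resistance is $R_t = R + R_p$. The parallel $R_p\!-\!C$ branch is what
   gives the model the negative frequency dependence of resistance typical
   of obstructive disease; a plain series RIC circuit cannot express it.
4. **Cohort statistics**: normality-gated two-group comparisons and Pearson
   correlations with verbal classification bands.
5. A **virtual-subject generator** that synthesizes complete FOT sessions
   from eRIC loads, so that every stage of the chain can be verified
   against known ground truth without clinical data.

## Spectral estimation choices

Exams are 16 s at 256 Hz (4096 samples); 256 Hz keeps a four-fold margin
above the 32 Hz top of the excitation grid. The estimator splits each
record into 4 s segments with 50% overlap (7 segments), removes each
segment's mean, applies a periodic Hann window, and averages the raw cross-
and auto-spectra across segments. Two properties motivate the 4 s segment:
its 0.25 Hz resolution places every excitation line exactly on an FFT bin,
and a periodic Hann window's transform vanishes at all integer bin offsets
beyond one, so in the noise-free case neighbouring excitation lines do not
leak into one another at all — the estimated transfer function is exact
there, which the tests exploit.

Grid readout takes the single FFT bin nearest each requested frequency; no
band averaging is applied. The squared coherence is computed from the same
averaged spectra, $\gamma^2 = |\bar G_{PV}|^2/(\bar G_{PP}\bar G_{VV})$;
with fewer than two segments it would be identically one, hence the
estimator refuses records that short.

**Quality gate.** An exam is retained only if $\gamma^2 \ge 0.9$ at *every*
grid frequency in the analysis band. The gate band is 4-32 Hz: the 2 Hz
line sits closest to the breathing fundamental and is not consumed by any
index, so it is reported but exempt. The final spectrum is the per-frequency
arithmetic mean of the accepted exams' complex values; its coherence is the
per-frequency minimum across exams, a deliberately conservative summary.
Breathing interference is handled by this frequency separation (the
excitation lines sit at least a factor 20 above a 0.2 Hz breathing rate)
and by the windowed averaging, not by an explicit high-pass filter.

## Index definitions and conventions

* **R0, S** — ordinary least squares of resistance on frequency over the
  seven grid points 4-16 Hz.
* **fr** — the lowest frequency in 4-32 Hz where the reactance crosses zero
  from negative to positive, located by linear interpolation between the
  bracketing grid points (grid snapping is available via a flag). If the
  reactance never makes that crossing, fr is absent (`NA`), not an error;
  in severely obstructed synthetic subjects the crossing can exceed 32 Hz.
* **Xm** — the plain arithmetic mean of the reactance over the 4-32 Hz grid
  points (an unweighted grid mean, not a frequency-weighted one).
* **Ax** — the trapezoidal integral over 4-32 Hz of $\max(0, -X(f))$. Using
  the negative part rather than integrating "up to fr" makes Ax
  well-defined even when the reactance re-dips or never crosses zero, and
  the two conventions agree whenever the reactance is monotone through a
  single crossing.
* **Cdyn, R4, Zrs4** — point readings at 4 Hz. When $X(4) \ge 0$ the
  elastic interpretation of the 4 Hz reactance breaks down and Cdyn is
  returned as `NA` with a warning.

Indices are computed on the averaged spectrum (average exams first, then
derive indices), not by averaging per-exam indices.

## Fitting the eRIC model

The fit minimizes the unweighted sum over the fitting band of squared real
plus squared imaginary residuals with the Levenberg-Marquardt algorithm
(`minpack.lm`). Positivity of all four elements is enforced by optimizing
their logarithms, with wide box bounds ($10^{\pm7}$) to keep iterates
finite. The default fitting band is 4-32 Hz, matching the band the indices
use and excluding the breathing-contaminated 2 Hz line; 2-32 Hz is a
configuration switch. Iteration cap 500, relative tolerance $10^{-10}$; the
convergence flag, iteration count and the final gradient norm (central
differences at the solution) are always reported.

The default starting point is data-driven: $R$ from the highest-frequency
resistance, $R_p$ from the low-frequency resistance excess, $C$ from the
4 Hz reactance (a Cdyn-type reading) and $I$ from the highest-frequency
reactance. When the peripheral branch is weakly expressed this surface has
shallow local minima, so when no explicit starting point is supplied the
fitter runs a small fixed set of four deterministic starts (the data-driven
guess, a physiological default, and two rescaled variants) and keeps the
best final objective; with an explicit `init` a single descent is performed
so that the result is a pure function of `(spectrum, init)`.

Goodness of fit is reported two ways, both over the fitting band:

* **total error** — the square root of the *sum* of squared real and
  imaginary errors (a raw sum, not a per-line RMS; the RMS variant exists
  behind `per_line = TRUE` but is never the default);
* **relative distance** — the mean over the band of the complex error
  magnitude normalized by the measured impedance modulus, in percent.

## The virtual-subject generator

The generator is the package's study population. One subject is an eRIC
load drawn from a cohort profile, plus three synthesized 16 s exams.

**Excitation.** Equal-amplitude cosines on the 2-Hz grid with uniform
random phases, rescaled so the peak pressure equals the profile amplitude
(1 cmH2O by default). The flow response is constructed line by line through
the admittance $1/Z(f)$ — exact for a periodic multisine, avoiding any
time-domain filter design. With noise and breathing disabled the
pressure-to-flow transfer therefore equals $1/Z$ exactly at every line,
which is the contract the recovery tests rest on.

**Disturbances.** Spontaneous breathing is a 0.2 Hz flow sinusoid of 0.3
L/s peak plus a first harmonic at 30% amplitude — quiet tidal breathing
through a mouthpiece. Measurement noise is white Gaussian per channel, SD
0.02 cmH2O on pressure and 0.005 L/s on flow, levels at which a
well-functioning FOT rig keeps coherence near unity, so exams fail the 0.9
gate only occasionally. The generator deliberately does *not* model
upper-airway shunting (experimentally minimized by cheek support in
practice), loudspeaker or pneumotachograph dynamics, nonlinear mechanics,
or within-breath variation — so passing tests say nothing about those
real-data effects.

**Parameter laws.** Each element is log-normal (positive by construction),
independent across elements, configured by median and log-scale in
`inst/extdata/profiles.yaml` — configuration, not code. The control profile
medians (R = 1.8, Rp = 1.2 cmH2O/L/s, I = 0.008 cmH2O/L/s², C = 0.020
L/cmH2O) were chosen so that a typical control subject shows
healthy-adult-like oscillometry: R0 near 2.8 cmH2O/L/s, resonance near
10.7 Hz, mildly negative low-frequency reactance, Cdyn near 0.12 L/cmH2O.
A load with $R_p^2 C \le I$ has nonnegative reactance everywhere — no
resonance and no defined Cdyn — so control medians were explicitly placed
on the physiological side of that boundary. The CF profile keeps a raised
peripheral resistance (median 3.2), reduced inertance (0.005) and strongly
reduced compliance (0.006), the compartmental signature of obstructive,
secretion-laden small airways with stiffened parenchyma.

**Calibration.** The CF central-resistance law is not set by hand: the
profile carries population targets for the regression intercept R0 (mean
4.71, SD 1.52 cmH2O/L/s — the published CF group level), and
`calibrate_profile()` solves for the R law that meets them. Because R
enters R0 additively and independently of the parallel branch, the required
moments are `mean(R) = target mean − mean(G)` and
`var(R) = target var − var(G)`, where G is the parallel-branch intercept
contribution, estimated once by a fixed-seed 20,000-draw Monte Carlo with a
closed-form R0 per draw; the log-normal matching those moments is then
exact. Calibration fails loudly when the targets are unreachable (mean
below the parallel-branch contribution, or SD below the spread the Rp and C
laws already induce).

## Statistics layer

Each variable is screened per group with the Shapiro-Wilk W test at level
0.05 (the gate level is a package choice); if both groups pass, a pooled
two-sample Student's t test is used, otherwise the Mann-Whitney U test
(normal approximation with continuity correction). Two-sided p values,
significance at p < 0.05, no multiple-testing correction. Pearson
correlations carry the verbal bands used in pulmonary function research,
resolved half-open and closed on the right: |r| in [0, 0.25] small or
none, (0.25, 0.50] reasonable, (0.50, 0.75] moderate to good, (0.75, 1]
very good to excellent. A paired (matched) Wilcoxon contrast has no
within-subject design in this package's scope and is not implemented.

## Numerical and reproducibility choices

* All randomness flows from user-supplied seeds through one helper that
  sets and restores the RNG state; cohort and exam seeds are derived
  substreams, so subjects, exams and whole pipeline runs are pure functions
  of their seeds.
* Text formats (exam CSV, spectrum/fit/report JSON) serialize doubles at 17
  significant digits, so every reader/writer pair round-trips exactly; the
  report writer uses fixed key order and is byte-stable.
* Noisy-recovery simulations add complex Gaussian noise with the quoted SD
  per quadrature component (real and imaginary independently).
* Problem sizes used by the test suite — cohorts of 23 controls and 27 CF
  subjects, 16 s exams, 50-100 Monte-Carlo replicates, 1000 null
  simulations for the type-I check — are the package's chosen study
  conditions and keep the full suite under a minute on one core.

## Limitations

The generator's cohort contrasts are constructed, not observed: group
separations mirror the direction and rough magnitude of published CF versus
control differences, but correlation structure between elements (set to
independence here) and any real-data artefacts (shunt, nonlinearity,
non-stationary breathing) are absent. The calibration pins only the R0
moments of the CF profile; all other population moments are plausible
choices, not estimates. Conclusions about the *method* — estimator
accuracy, gate behaviour, fit identifiability, statistical gating — carry
over to real data; conclusions about *populations* do not.
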