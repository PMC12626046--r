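---
title: "Models and methods for hybrid TD-NIRS + DCS session analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for hybrid TD-NIRS + DCS session analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsdcs)
```

This vignette is the package's own account of the science it implements:
the forward models, the inverse fits, the biomarker definitions, the
quality-control logic, and — importantly — the choices we made wherever a
published device description leaves the numerical details open.

## The measurement being modelled

A hybrid diffuse-optics monitor combines two channels on one probe:

* **TD-NIRS** pulses two lasers (685 and 828 nm, 53 MHz) into tissue and
  histograms the arrival delays of diffusely reflected photons at a
  source-detector separation of 2.5 cm, producing one distribution of
  times of flight (DTOF) per wavelength per second. The DTOF shape
  carries the absolute absorption coefficient μa (decay of the tail) and
  reduced scattering coefficient μs′ (width and delay of the peak).
* **DCS** shines long-coherence 785 nm light and records the intensity
  autocorrelation g₂(τ) of the detected speckle every 26 ms. Moving red
  blood cells decorrelate the speckle; the decay rate of g₂ quantifies
  microvascular blood flow.

Two-wavelength μa yields hemoglobin concentrations and the microvascular
oxygen saturation StO₂; DCS yields the blood-flow index BFI. Around a
vascular occlusion test (VOT) these become reactivity biomarkers, and at
baseline they combine with pulse-oximeter SpO₂ into a Fick-law metabolic
index.

## Forward models

### Time-resolved reflectance

`simulate_reflectance_curve()` implements the semi-infinite homogeneous
diffusion approximation with the extrapolated-boundary condition: an
isotropic point source at depth $z_0 = 1/\mu_s'$ and a negative image
source mirrored about $z = -z_b$, $z_b = 2AD$, $D = 1/(3\mu_s')$. The
boundary coefficient $A = (1+R_\mathrm{eff})/(1-R_\mathrm{eff})$ uses the
Egan–Shu polynomial for the effective Fresnel reflection at refractive
index $n$ (default 1.4, giving $A \approx 3.25$). Conventions in the
literature for $A$ differ by a few percent; this only rescales $z_b$ and
has negligible effect on recovered properties at ρ = 2.5 cm.

Two analytic properties anchor the test suite:

* the late-time log-slope converges to $-\mu_a v$ ($v = c/n$). The
  convergence is slow — the $t^{-5/2}$ spreading term contributes
  $-\tfrac{5}{2t}$ to the slope, still ~3% of $\mu_a v$ at 15 ns — so the
  property test evaluates the slope on an extended 60 ns grid where the
  residual term is below the 2% tolerance;
* the first moment (mean time of flight) strictly decreases with μa,
  checked numerically.

### DTOF synthesis

`generate_dtof()` convolves the theoretical curve with the instrument
response function **circularly over the laser period**, exactly as a
histogrammer synchronised to a 53 MHz pulse train wraps late photons into
early bins. The signal is scaled to a target photon count (10⁶/s is the
equalisation target of the modelled device), a uniform dark floor is
added, and each bin receives an independent Poisson draw. With a
delta-function IRF, zero dark and noise disabled the output reproduces
the analytic curve bin for bin — the identity the test suite pins down.

The published description of the modelled device does not state the
histogrammer's bin width or span, so the grid is a package default: 2048
bins spanning one 18.868 ns period (~9.2 ps/bin), configurable through
`forward_model_spec()`. The default IRF is a 200 ps FWHM Gaussian
centered at 3.9 ns, matching the barycenter scale such devices report.

### Correlation diffusion and g₂

`g1_semiinf()` is the continuous-wave correlation-diffusion Green's
function for the same semi-infinite geometry with Brownian-motion
dynamics, in which the blood-flow index BFI = $\alpha D_b$ (cm²/s) scales
the decay: $K(\tau)^2 = 3\mu_a\mu_s' + 6\mu_s'^2 k_0^2 \,\mathrm{BFI}\,
\tau$. The Siegert relation $g_2 = 1 + \beta |g_1|^2$ closes the model;
β = 0.5 is the ideal single-mode-detection value for unpolarised light
and the generator's default.

The dual-source injection geometry of the modelled probe (two points on
a 3.5 mm arc, both centered at 2.5 cm) is collapsed to a single effective
separation; the doubled detected intensity enters only as a count-rate
factor. No correlator noise model is published for the device, so the
generator uses zero-mean Gaussian per-lag noise with standard deviation

$$\sigma(\tau) = s \cdot \frac{1 + \beta |g_1(\tau)|^2}{\sqrt{N}},
\qquad N = \text{count rate} \times \text{averaging time},$$

the leading behaviour of photon-limited correlator noise: proportional to
the curve level and shrinking with detected photons. The amplitude
$s = 3$ was chosen once so that a 1 s average at 50 kHz has
$\sigma \approx 0.02$ near $\tau \to 0$, a realistic figure for hardware
correlators; it is not adjusted per experiment. Values are deliberately
not clipped, so noise can carry g₂ slightly outside $[1, 1+\beta]$ as
real estimators do.

## Inverse fits

### DTOF convolution fit

`fit_dtof()` minimises the Poisson-weighted squared difference between
the background-subtracted DTOF and (model ⊛ IRF) over amplitude, μa and
μs′. Numerical choices:

* **background**: mean and sd over a pre-peak window (up to 100 bins),
  restricted to the first half of the region before the signal reaches
  1% of its peak so the rising edge never leaks into the estimate; the
  sd also defines the dynamic range DR = max(DTOF)/sd(background);
* **fit window**: 80% of peak on the rising edge to 1% of peak on the
  falling edge, a common TD-NIRS convention; configurable;
* **optimizer**: Levenberg–Marquardt (`minpack.lm::nls.lm`) on
  (log μa, log μs′) with the amplitude profiled analytically at each
  step; initialisation μa = 0.1 cm⁻¹, μs′ = 10 cm⁻¹; relative-objective
  tolerance 1e-10, maximum 200 iterations. Non-convergence is flagged in
  the diagnostics, never raised;
* **weights**: $1/\max(y_i, 1)$, the standard Poisson approximation.

Because the same forward model generates and fits the synthetic data, a
noiseless fit is an identity check (recovered to optimizer tolerance),
and the 20-repetition phantom experiment at 10⁶ counts measures only the
noise-induced dispersion: mean recovered values stay well within 5% of
the nominal phantom properties at both wavelengths. A brute-force grid
search over the exposed `dtof_objective()` cross-checks that the LM
optimum is the actual minimum.

### Chromophores

`compute_chromophores()` solves the 2×2 system
$\mu_a(\lambda) - w f_{H_2O}\mu_{a,\mathrm{water}}(\lambda) =
\ln 10\,(\varepsilon_\mathrm{HbO} C_\mathrm{HbO} +
\varepsilon_\mathrm{HbR} C_\mathrm{HbR})$ at 685/828 nm. The extinction
table (molar, decadic) is a versioned package constant taken from the
standard OMLC compilation at the three device wavelengths, with water
absorption in the Hale–Querry range; the water volume fraction defaults
to 0 for the solid phantom and 0.7 for muscle. Negative concentrations
(non-physical spectra) are returned with a warning flag rather than an
error, since downstream QC wants to see them. The solid phantom contains
no hemoglobin, but running its per-repetition μa pairs through the same
inversion (water term zero) yields "effective" tHb and StO₂ values whose
session-to-session drift is a sensitive whole-chain stability metric
(`compute_phantom_effective()`, `phantom_trending()`).

### g₂ fit

`fit_g2()` fits β and BFI jointly — matching devices that report
per-measurement β statistics — with box constraints β ∈ (0, 1]. After a
first pass over all lags, the fit restricts itself to lags where the
fitted model retains more than 1% of its decay and refits. Optical
properties at 785 nm are linearly interpolated in wavelength from the
fitted 685/828 nm values (`interp_props()`); the interpolation rule is a
package choice, as hybrid devices do not publish one. A flat curve (no
decay) returns a non-converged result instead of raising. A deliberate
property test fits curves generated with μa perturbed by +20% against
the unperturbed value and asserts a consistent, non-zero BFI bias — a
guard against silently mixing up property tables between modules.

## VOT trajectory and biomarkers

`simulate_vot_timecourse()` emits the canonical VOT shape: a baseline
plateau; linear desaturation at `desat_rate` (floored at `min_sto2`)
during occlusion; on release, a linear rise at `reo2_rate` to the
hyperemic peak, then exponential relaxation back to baseline. The
relaxation is a *shifted* exponential that reaches baseline exactly at
the end of the recovery window: a pure exponential never crosses its
asymptote, which would make the area-under-curve definition (first to
second baseline crossing) vacuous on noiseless traces. With the shifted
form, all biomarkers of a noiseless trace close on their generating
values to better than 1%, which the suite asserts.

Generator defaults are healthy-adult forearm values: baseline StO₂
70.3%, BFI 0.53·10⁻⁸ cm²/s, DeO₂ −4.1 %/min, ReO₂ 1.1 %/s, hyperemic
peak +8% StO₂ and 5× BFI, relaxation constant 55 s, channel noise 0.5%
StO₂ and 12% relative BFI. They were fixed once from typical published
muscle-VOT figures and are not tuning knobs.

Extraction rules (`vot_biomarkers()` and the underlying functions):

* baselines: mean over the 30 s immediately preceding inflation; the
  recovery ("second") baseline is the mean over the final 60 s of
  recovery — the reference publication distinguishes the two baselines
  without defining the second's window, so the 60 s tail is a package
  decision;
* DeO₂: OLS slope over the first 60 s of occlusion, reported per
  minute; ReO₂: OLS slope from the last minimizing StO₂ sample (ties
  broken to the latest occurrence before deflation) to the first sample
  at or above the recovery baseline, reported per second. Units are
  fixed regardless of sampling rate;
* AUC: trapezoidal integral of (signal − recovery baseline) between
  baseline crossings located by linear interpolation. Both crossings are
  anchored around the excursion peak (last upward crossing before it,
  first downward after it) so channel noise near the baseline cannot
  truncate the hyperemic lobe. A signal that never exceeds the baseline
  has zero area; an excursion that never closes is excluded. The AUC is
  referenced to the recovery baseline for both channels — the schematic
  figures are ambiguous between the two baselines, and the recovery
  baseline is the one the crossing definition names;
* exclusion: recoveries whose recovery baseline falls more than 5%
  (relative, configurable) below the pre-occlusion baseline are marked
  incomplete, and ReO₂/AUC are excluded rather than reported.

`compute_metabolism()` implements MMRO₂ = [Hb]·(SpO₂−StO₂)/(γ·SpO₂)·BFI
and OEF = 100·(SpO₂−StO₂)/(γ·SpO₂). The OEF formula is not printed in
the device literature; this definition is the natural Fick-law companion
and reproduces published healthy-cohort OEF values (~28%) with γ = 1.
The venous fraction γ defaults to 0.75, the common convention, and is
exposed everywhere it enters.

## Quality assessment and trending

The quality phase alternates 10 s laser ON/OFF segments after a TD-NIRS
equalisation minute. `evaluate_qp()` compares per-segment mean count
levels against the thresholds: DCS dark < 2 kHz, signal within
10–200 kHz, cross-talk dark < 3 kHz with the TD-NIRS laser active;
TD-NIRS per-wavelength signal within 0.8–1.2 Mcps and dark < 30 kcps;
the oximeter verdict mirrors the manufacturer validity flag. Whether the
stated bounds are open or closed is not specified in the device
literature; here one-sided dark maxima are strict (<) and signal bands
are pass-inclusive at their edges, and segment means use the central 8 s
of each segment to avoid switching transients. Any failing indicator
sets the blocking flag. The evaluation is a pure function of the segment
levels — permuting segment order cannot change a verdict, which is
tested.

The QP generator's default levels encode the interference structure such
hybrid devices actually show: the TD-NIRS background rises measurably
when the DCS laser emits (cross-talk 15 kcps against a 10 kcps dark
floor), while the DCS background is unaffected by the TD-NIRS lasers.
`qp_interference()` recovers exactly that pattern with Mann–Whitney
tests, and a 500-simulation null study pins the test's type-I error to
0.05 ± 0.02.

## Precision statistics

All coefficients of variation use the sample (n−1) standard deviation;
CV of a zero-mean series is flagged undefined rather than returned as
infinity. `test_retest()` separates within-repositioning from
between-repositioning variability (5 blocks of 200 s in the simulated
protocol, with between-block terms set to produce ~1.2% StO₂ and ~12.6%
BFI inter-block CVs). `lop_precision()` evaluates per-step CVs over the
final 15 s of each graded-occlusion interval and correlates them with
mean values and signal-quality indices by Spearman rank correlation
(exact p below n = 10, large-sample approximation above).
`bland_altman()` reports bias, ±1.96 sd limits and the OLS
proportional-bias slope of difference on mean. `resample_to_device()`
mimics a slow display device by sample-and-hold (nearest preceding
sample), with linear interpolation behind a flag.

## Sessions and reproducibility

Sessions are plain-text directories: a YAML manifest (format version,
seed, protocol, channel registry with units and cadence) plus one CSV
per channel; DTOF and g₂ arrays are wide tables. Text-first storage
keeps every fixture reviewable; the native format of any particular
instrument is undocumented, so the package defines its own. Readers
reject newer major format versions, error on corrupted tables naming the
file and row, and warn about unregistered files. All randomness derives
from a single session seed through a documented affine splitting scheme
(`split_seed()`), making every fixture bit-reproducible.

## What the synthetic data does and does not show

The generators reproduce the statistical structure the analysis assumes:
Poisson counting noise, count-rate-scaled correlator noise, Gaussian
channel noise, and the schematic VOT trajectory. Passing tests therefore
demonstrate the *inverse pipeline's* correctness and noise behaviour —
not the adequacy of the diffusion approximation to layered real tissue,
nor detector afterpulsing, IRF drift within a session, motion artifacts,
or cardiac pulsatility in BFI (unresolved at the 1 Hz analysis rate and
deliberately not simulated). Recovery experiments are also "inverse
crimes": the same forward model generates and fits the data, so they
quantify precision under noise, not model misspecification bias.

## Problem sizes

The shipped experiments are sized for a laptop: 20 DTOF repetitions per
wavelength at 10⁶ counts for phantom recovery, 60 one-second g₂ curves
for coherence-factor recovery, 8 seeds per count level for the
dispersion-monotonicity check, 5 instances for the grid-search oracle,
and 500 simulations for the rank-test calibration. The full test suite
runs in well under a minute.
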