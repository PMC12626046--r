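# nirsdcs

Simulation and analysis of hybrid diffuse-optics monitoring sessions that
combine **time-domain near-infrared spectroscopy (TD-NIRS)** and **diffuse
correlation spectroscopy (DCS)** on skeletal muscle. The package is aimed
at instrument builders and biomedical-optics researchers who need a tested,
end-to-end software stack for such a device: forward models of what the
hardware records, the inverse fits that turn raw histograms and
autocorrelations into physiology, vascular-occlusion-test (VOT) biomarkers,
instrument quality control, and the precision/agreement statistics used to
validate a clinical monitor.

## What it computes

**TD-NIRS.** The device histograms photon times of flight (DTOF) at 685 and
828 nm, 53 MHz repetition rate, at a source-detector separation of
ρ = 2.5 cm. The forward model is the semi-infinite homogeneous diffusion
approximation with extrapolated boundary,

    R(ρ,t) ∝ t^(-5/2) exp(-μa v t - ρ²/(4 D v t)) ·
             [ z0 e^(-z0²/4Dvt) + (z0+2zb) e^(-(z0+2zb)²/4Dvt) ],

with D = 1/(3 μs′), z0 = 1/μs′, zb from the extrapolated-boundary
coefficient. `fit_dtof()` convolves this with the measured instrument
response function (IRF) and recovers absolute μa and μs′ by
Levenberg–Marquardt least squares with Poisson weights. Two-wavelength
absorption then yields HbO, HbR, tHb and StO₂ = 100·HbO/tHb through a 2×2
extinction-coefficient inversion (`compute_chromophores()`).

**DCS.** A hardware correlator records the intensity autocorrelation
g₂(τ) = ⟨I(t)I(t+τ)⟩/⟨I⟩² every 26 ms at 785 nm. Via the Siegert relation
g₂ = 1 + β|g₁|², `fit_g2()` jointly fits the coherence factor β (≈0.5 for
single-mode detection) and the blood-flow index BFI = αD_b that scales the
decay of the correlation-diffusion field autocorrelation g₁.

**VOT biomarkers.** From a baseline / arterial-occlusion / recovery
protocol (3 min / 3 min / 5 min, cuff at systolic + 50 mmHg),
`vot_biomarkers()` extracts the desaturation slope DeO₂ (%/min, first
minute of occlusion), the resaturation slope ReO₂ (%/s, from the StO₂
minimum to the recovery baseline), hyperemic areas under the curve for
StO₂ (%·min) and BFI (cm²), and the Fick-law metabolism indices
MMRO₂ = [Hb]·(SpO₂−StO₂)/(γ·SpO₂)·BFI and OEF.

**Quality and precision.** `evaluate_qp()` applies the laser ON/OFF
quality-assessment-phase thresholds (dark, signal and cross-talk count
bands), `qp_interference()` runs the Mann–Whitney interference checks,
`phantom_trending()` tracks IRF/phantom stability across sessions, and the
stats module provides CV, test-retest, graded-occlusion precision,
Bland-Altman agreement and rank-based group comparison.

**Synthetic data.** Every input the pipeline consumes can be simulated
with the statistical structure the analysis assumes — Poisson counting
noise on DTOFs, count-rate-dependent g₂ noise, Gaussian channel noise on
physiologic traces — and written to a plain-text session directory
(`simulate_session()` / `read_session()`).

## Worked example

```r
library(nirsdcs)
geom <- probe_geometry()            # rho 2.5 cm, 685/828 nm, 785 nm DCS
spec <- forward_model_spec()        # 2048 bins over one 53 MHz period

# phantom DTOF at 1e6 counts, fitted back
irf <- gaussian_irf(spec, noise = FALSE)
d   <- generate_dtof(phantom_preset(685), irf, geom, spec,
                     total_counts = 1e6, dark_rate = 1000, seed = 1)
fit_dtof(d, irf, geom)
#> DTOF convolution fit (685 nm)
#>   mua  = 0.2303 cm^-1
#>   musp = 12.799 cm^-1
#>   reduced chi2 = 1.089, DR = 2.67e+04, converged in 6 iterations
```

The nominal phantom values are μa = 0.23 cm⁻¹ and μs′ = 12.8 cm⁻¹: the fit
recovers them to a fraction of a percent at realistic counting noise. The
reduced χ² near 1 says the Poisson noise model is consistent; DR is the
dynamic range (DTOF maximum over background standard deviation).

```r
# healthy-muscle absorption -> hemoglobin and saturation
compute_chromophores(optical_properties(0.22, 8.62, 685),
                     optical_properties(0.23, 8.18, 828),
                     water_fraction = 0.7)
#> HbO 71.61 uM, HbR 30.55 uM, tHb 102.16 uM, StO2 70.1%

# a one-second g2 curve at 50 kHz, fitted for BFI and beta
p785 <- healthy_muscle_preset(785)
g <- generate_g2(p785, bfi = 1e-8, beta = 0.5, geom, spec,
                 count_rate = 50, avg_time = 1, seed = 7)
fit_g2(g, p785, geom)
#> g2 fit: BFI = 1.018e-08 cm^2/s, beta = 0.510 (chi2_r 0.000396, converged)

# a full noisy VOT and its biomarkers
tr <- simulate_vot_timecourse(phys = vot_physiology(), seed = 5)
vot_biomarkers(tr, spo2 = 99, hb_gdl = 13.5, gamma = 0.75)
#> VOT biomarkers
#>   baseline StO2 70.3%, baseline BFI 5.453e-09 cm^2/s
#>   DeO2 -4.29 %/min, min StO2 57.2%
#>   ReO2 0.97 %/s, AUC StO2 6.27 %.min, AUC BFI 1.103e-06 cm^2
#>   OEF 38.7%, MMRO2 2.846e-08 %.cm^2/s (gamma 0.75)
```

The extracted DeO₂/ReO₂ sit near the generating physiology (−4.1 %/min,
1.1 %/s) with the residual spread coming from the injected channel noise.

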