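# dcsflow

Analysis tools for **diffuse correlation spectroscopy (DCS)** monitoring of
cerebral microvascular blood flow, aimed at the setting where flow
*variability* — not mean flow — is the signal of interest: detecting the
hemodynamic instability that precedes and accompanies germinal-matrix
bleeding (intraventricular hemorrhage, IVH) in premature neonates and their
preclinical models.

The package is for researchers who have (or want to simulate) continuous
1 Hz DCS recordings around an insult, and who want a tested, reproducible
route from raw intensity autocorrelation curves to trend statistics:

* **Forward model** — the semi-infinite correlation diffusion solution with
  Brownian scatterer dynamics. The normalized field autocorrelation is

      g1(τ) = [exp(−K(τ)r1)/r1 − exp(−K(τ)rb)/rb] /
              [exp(−K(0)r1)/r1 − exp(−K(0)rb)/rb],

      K(τ) = sqrt(3 µa µs′ + 6 µs′² k0² · BFi · τ),

  with extrapolated-boundary geometry (r1, rb from z0 = 1/µs′ and
  zb = 2(1+R_eff)/(3µs′(1−R_eff))), and the Siegert relation
  g2(τ) = 1 + β·g1(τ)². BFi (≡ αDb, cm²/s) is the blood flow index.
* **Inversion** — per-second least-squares fits of measured g2(τ) for
  (BFi, β), with β profiled out in closed form; 8-s centered moving-mean
  smoothing of the fitted trace.
* **Variability inference** — coefficient of variation CV = σ/µ in
  consecutive 5-minute windows anchored at the injection/insult, per-subject
  and pooled OLS slope of CV against time with t-tests.
* **Spectral analysis** — Welch spectra of the CBFi trace, normalized over
  0.002–0.4 Hz, plus across-subject averaging.
* **Motion control** — min-max-scaled 3-axis accelerometry, its 3-D
  magnitude, CV_accel, and a flow/motion independence regression.
* **Echogenicity** — mean-pixel-intensity ratios in elliptical ultrasound
  ROIs against a reference frame.
* **Synthetic data** — a fully seeded generator for every input above:
  band-limited (< 0.25 Hz) flow fluctuations whose amplitude ramps after a
  simulated injection, noisy g2 curve emission, motion independent of flow
  by construction, a viscosity-controlled Brownian optical phantom, and
  speckle image series with a brightening ventricular ROI.

Default constants throughout are the acquisition world the package targets:
µa = 0.1 cm⁻¹, µs′ = 8.0 cm⁻¹, λ = 785 nm, ρ = 5 mm, 1 Hz sampling,
8 s smoothing, 5 min CV windows, 0.002–0.4 Hz spectra.

## Worked example

```r
library(dcsflow)

optics <- optical_config()   # the default acquisition constants
optics
#> DCS optical configuration
#>   mu_a        0.1 cm^-1
#>   mu_s'       8 cm^-1
#>   wavelength  785 nm
#>   n_medium    1.4
#>   rho         0.5 cm

# invert one noiseless synthetic curve: exact recovery of (BFi, beta)
tau   <- dcs_lag_grid()
curve <- correlation_curve(0, tau, g2_model(tau, flow_state(1e-8, 0.5), optics))
fit   <- fit_g2_curve(curve, optics)
#> bfi_hat = 1.000000e-08 cm^2/s, beta_hat = 0.5000, converged = TRUE

# an end-to-end synthetic "injected cohort" session
cfg <- session_config(seed = 42, n_subjects = 2, injection_time_s = 100,
                      scenario = scenario_config(seed = 42, duration_s = 1300,
                                                 baseline_s = 100),
                      out_dir = file.path(tempdir(), "demo"))
run_session(cfg)
#> DCS session report (synthetic mode, 2 subject(s))
#> pooled CV slope: slope 0.003535 +/- 0.000325 (SE), t = 10.9, p = 3.58e-05, n = 8
#> flow/motion independence: slope 0.08956 +/- 0.4521 (SE), t = 0.198, p = 0.861, n = 4
#> echogenicity ratios: 1, 1.48, 2.76
#> outputs in /tmp/.../demo
```

Reading the report: the generator ramps the target flow CV from 0.05 to
0.20 after the simulated injection, and the pooled regression recovers a
significantly positive CV trend (≈ 0.0035 CV/min over these 1200 s records,
p ≪ 0.05) — the signature of progressive flow destabilization. Motion CV
does not predict flow CV (p = 0.86), as it must, since the motion stream is
generated independently. The echogenicity ratios track the injected
brightening schedule {1.0, 1.5, 2.8} to within speckle noise.

A command-line interface with subcommands `simulate`, `fit`, `analyze`,
`echo` and `report` is installed at `inst/cli/dcsflow`
(`Rscript <library>/dcsflow/cli/dcsflow report --seed 1 --out-dir out`).

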