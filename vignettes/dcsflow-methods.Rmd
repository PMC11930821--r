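---
title: "Models and methods in dcsflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dcsflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcsflow)
```

# The measurement and the model

Diffuse correlation spectroscopy infers microvascular blood flow from the
temporal decorrelation of coherent near-infrared light multiply scattered by
moving red blood cells. A photon-counting correlator reports the normalized
intensity autocorrelation $g_2(\tau)$; the physics lives in the field
autocorrelation $g_1(\tau)$, connected through the Siegert relation
$g_2 = 1 + \beta g_1^2$, where $\beta \in (0, 1]$ is fixed by the detection
optics (single-mode fiber collection gives $\beta \approx 0.5$).

`dcsflow` models the head as a semi-infinite homogeneous turbid medium and
red-cell motion as effective Brownian diffusion with mean-square
displacement $\langle \Delta r^2(\tau) \rangle = 6 \,\mathrm{BFi}\, \tau$.
The correlation diffusion equation then has the closed-form
extrapolated-boundary solution

$$ g_1(\tau) = \frac{e^{-K(\tau) r_1}/r_1 - e^{-K(\tau) r_b}/r_b}
                   {e^{-K(0) r_1}/r_1 - e^{-K(0) r_b}/r_b}, \qquad
   K(\tau) = \sqrt{3\mu_a \mu_s' + 6 \mu_s'^2 k_0^2\, \mathrm{BFi}\, \tau}, $$

with $z_0 = 1/\mu_s'$, $z_b = \tfrac{2}{3}\,(1+R_{\mathrm{eff}}) /
(\mu_s'(1-R_{\mathrm{eff}}))$, $r_1 = \sqrt{\rho^2 + z_0^2}$,
$r_b = \sqrt{\rho^2 + (z_0 + 2 z_b)^2}$ and $k_0 = 2\pi n/\lambda$.
$R_{\mathrm{eff}}$ comes from the standard polynomial in the relative
refractive index. The blood flow index BFi ($\equiv \alpha D_b$, cm²/s) is
a *relative* flow measure; no absolute calibration to mL/100 g/min is
attempted.

Assumptions worth keeping in mind: homogeneous optical properties held fixed
at $\mu_a = 0.1$ cm⁻¹ and $\mu_s' = 8.0$ cm⁻¹ during fitting (errors in
these bias BFi multiplicatively but barely distort *relative* trends);
Brownian rather than ballistic dynamics (empirically the right regime for
tissue); a semi-infinite geometry, reasonable at $\rho = 5$ mm on a neonatal
head but never exact.

## Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| `mu_a` | 0.1 | cm⁻¹ | acquisition constant of the targeted measurements |
| `mu_s_prime` | 8.0 | cm⁻¹ | same |
| `wavelength` | 785 | nm | same |
| `rho` | 0.5 | cm | same (5 mm probe) |
| `n_medium` | 1.4 | — | conventional soft-tissue value; **not** stated for this preparation, so it is configurable and declared, not inferred |
| lag grid | $10^{-7}$–$10^{-1}$ s, 64 pts/decade | s | emulates multi-tau hardware correlators; configurable |
| `smoothing_s` | 8 | s | stated acquisition processing (8-s moving mean at 1 Hz) |
| CV window | 300 | s | stated analysis window (5 min) |
| spectral band | 0.002–0.4 | Hz | stated analysis band |

# Fitting

The inversion minimizes $\sum_i (g_{2,\mathrm{model}}(\tau_i) -
g_{2,\mathrm{meas}}(\tau_i))^2$ over $(\mathrm{BFi}, \beta)$ with bounds
$\mathrm{BFi} \in [0, 10^{-5}]$ cm²/s (a generous physiologic ceiling) and
$\beta \in (0, 1]$. Two numerical choices matter:

* **Profiling.** At fixed BFi the model is *linear* in $\beta$
  ($g_2 - 1 = \beta g_1^2$), so the optimal $\beta$ has a closed form and
  the problem reduces to one dimension. BFi is then located by a coarse
  60-point log-spaced scan of $[10^{-12}, 10^{-5}]$ followed by
  golden-section/parabolic refinement on $\log_{10}\mathrm{BFi}$
  (`stats::optimize`, tol $10^{-11}$). The coarse scan plays the role of a
  multi-start safeguard: the profiled SSE is unimodal for clean curves, and
  the scan protects against flat shoulders under noise. This route achieves
  the $<10^{-6}$ relative round-trip accuracy a quasi-Newton box solver
  struggles to guarantee, which is why it was preferred.
* **Boundary handling.** The SSE at exactly $\mathrm{BFi} = 0$ is always
  checked; a curve with no resolvable decay (flat $g_2$) is assigned
  BFi = 0 rather than some tiny grid value. Optimizer failure is reported as
  `converged = FALSE`, never an error, so one bad second cannot kill a
  session.

Lags are used only while $g_2 - 1 > 0.01\,\beta_0$ ($\beta_0$ = early-lag
plateau estimate): the deep tail carries noise, not decay information. With
fewer than five such lags the full curve is used. A `fix_beta` option
freezes $\beta$ at the mean early-lag estimate of the first minute — the
original acquisition code may well have done either; both are exposed.

**Smoothing.** The "8-s moving mean" is realized as a centered window —
four samples before, the current sample, three after — with shrinking
windows at the record edges. A centered filter avoids phase lag, which
matters because CV windows are anchored in absolute time. Non-converged
points are excluded from every window (gap-aware averaging) instead of
propagating NA.

# Variability inference

CV is $s/\bar{x}$ with the *sample* (n−1) standard deviation — the stable
convention for 300-sample windows and the one the exact unit tests pin.
Windows are consecutive, non-overlapping, and anchored at the injection
time, so the first post-injection window starts at the anchor; the
pre-injection baseline can be windowed separately by re-anchoring. CV is
computed on the smoothed trace by default (smoothing precedes all
downstream analysis), switchable via `use_smooth`.

Trend inference is ordinary least squares of CV on window center with a
two-sided $t$-test on $n-2$ df. The pooled cohort fit treats all
subject-window points as exchangeable — no random effects, no clustering
correction — mirroring a pooled cohort presentation; per-subject fits are
always emitted alongside so the pooling assumption is auditable. Whether
pre-injection windows belong in the pooled fit is not decidable from the
stated analysis; the default excludes them (anchor = injection).

The flow/motion independence check is OLS of CV_CBFi on CV_accel over
matched 5-minute windows. Correlation at other temporal resolutions was a
plausible alternative; regression on the shared window grid was chosen so
both controls use identical machinery and its $t$-test calibration is
verified directly (type-I error within [0.04, 0.06] over 2000 null
simulations).

# Spectra

The estimator is a Welch periodogram: 500-s Hann-windowed segments, 50 %
overlap, per-segment linear detrend, one-sided scaling. 500 s resolves the
0.002 Hz band edge exactly (bin width 1/500 Hz places 0.002 and 0.1 Hz on
bins). Spectra are restricted to 0.002–0.4 Hz and normalized to unit
*in-band* sum — "normalized" is otherwise underdetermined, and unit sum
makes across-subject averaging well defined (averages are renormalized).
Constant traces are rejected before normalization rather than returning
0/0. The averaging function refuses mismatched grids instead of
interpolating.

# Accelerometry

Min-max scaling is global over the recording, not per window: the gains and
offsets it removes are placement artifacts, constant per session, and
rescaling per window would reintroduce them as window-to-window gain
noise. The 3-D magnitude of the scaled axes lives in $[0, \sqrt{3}]$. The
device rate is unstated; the generator default is 25 Hz, and the magnitude
is reduced to 1 Hz by per-second means so CV_accel shares the flow CV
window machinery exactly. The entire pipeline is affine-invariant per axis
(positive gains), which the acceptance suite asserts exactly.

# Echogenicity

The ROI is an axis-aligned ellipse rasterized at pixel centers
(`((r-cr)/ar)² + ((c-cc)/ac)² ≤ 1`, 0-based); degenerate semi-axes collapse
to the center pixel, and the mask is pinned against brute-force enumeration
in tests. The primary statistic is the *ratio of ROI means* (not the mean
of pixel ratios). The "± standard deviation" sometimes quoted alongside
such ratios is ambiguous; here it is mirrored as `pixel_ratio_sd` — the SD
of per-pixel ratios, computed only when the two masks are congruent — and
documented rather than asserted against any reference value. The reference
frame is configurable among earliest-timepoint, pre-injection, or
control-animal semantics, which are the two usages that coexist in
practice. Intensities are treated as linear; image I/O is plain-text
(ASCII PGM / CSV) because the toolchain is deliberately text-only — PNG and
TIFF readers are out of dependency scope here.

# The synthetic world

`simulate_bfi_timeseries` draws unit-variance Gaussian noise, band-limits
it to 0.01–0.25 Hz by FFT-domain masking (zeroing out-of-band bins
conjugate-symmetrically, then rescaling to unit variance), and modulates a
baseline BFi of $10^{-8}$ cm²/s as $\mathrm{BFi}(t) = \mathrm{BFi}_0 (1 +
a(t) z(t))$. The amplitude $a(t)$ *is* the target flow CV: constant at
`cv_start` (default 0.05) through a 300-s baseline, then ramping linearly
to `cv_end` (default 0.20) at the end of the 3900-s record. These defaults
state the emulated condition — variability that begins rising minutes after
the insult, spectrally concentrated below 0.25 Hz — and are not tuned to
test outcomes. Values clip at $\mathrm{BFi}_0/10$ to stay positive.

Curve emission applies multiplicative Gaussian noise to $g_2 - 1$ (default
σ = 0.02) rather than a full correlator shot-noise model: sufficient to
exercise the fit's robustness contracts, with the noise level an explicit
free parameter because the true correlator statistics are unknown. A
Koppel-type noise model is a clean future extension point.

The phantom emulates Brownian "flow" controlled by solution viscosity via
Stokes–Einstein scaling $D_b \propto 1/\eta$, parameterized by viscosity
directly — no glycerol-concentration-to-viscosity conversion is printed
anywhere authoritative, so none is implemented. Motion and image streams
use RNG seeds offset from the flow seed ($+10^6$, $+2\times10^6$) so the
three are independent by construction; everything is deterministic given
the scenario seed (R's Mersenne-Twister).

What the generator does **not** emulate: physiological autoregulation
dynamics, the nonlinear/critical-transition character of real hemorrhagic
events, correlated flow-motion artifacts (a real probe bump perturbs both),
heteroscedastic correlator noise, ultrasound speckle correlation. A green
test therefore establishes that the *analysis chain* is correct and
calibrated on data with the assumed statistical structure — not that the
biological effect itself is reproduced.

# Session orchestration

`run_session` chains fit → smooth → CV/slope → spectra → motion control →
echogenicity, writes every table as UTF-8 CSV, and echoes every tunable in
`report.json` so unstated-default audits are mechanical. Configuration is
JSON (`jsonlite`): a YAML surface was considered, but no YAML parser is
available in the supported dependency envelope and JSON loses nothing for
machine-written configs. Re-running with an identical seed and config is
byte-identical, which the test suite asserts on the emitted files.

# Known limitations

* Homogeneous semi-infinite model only; no layered or curved geometries,
  no time-domain or interferometric DCS variants.
* Pooled CV regression ignores within-subject correlation by design
  (transparency over sophistication at n = 5-scale cohorts); mixed-effects
  or mixture modelling of diverging trajectories is deliberately out of
  scope.
* The noisy-fit bias guarantee is Monte-Carlo-verified at the default noise
  model, not derived; strongly non-Gaussian correlator noise could bias the
  profile fit.
* Echogenicity quantification assumes a fixed, user-supplied ROI; there is
  no registration or automated ventricle segmentation.
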