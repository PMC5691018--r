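---
title: "Ion recombination corrections from signal strength: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ion recombination corrections from signal strength: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pioncal)
```

## The problem

Flattening filter-free (FFF) linac beams deliver a much higher dose per
pulse than flattened beams. In an ionization chamber this raises the ion
density in the collecting volume, more ions recombine before they are
collected, and the electrometer under-reads. The collection-efficiency
correction `Pion` multiplies the reading to recover the lost charge.

The standard way to measure `Pion` — Boag's two-voltage technique —
requires two readings at a fixed point, one at the normal bias voltage
and one at half of it. That is incompatible with how most commissioning
data are taken: depth-dose curves are scanned continuously at a single
voltage. `pioncal` implements the workaround of calibrating `Pion`
against the *signal strength itself* and then correcting single-voltage
scan data after the fact.

## The model

Three relations carry the whole package.

**Two-voltage estimate.** With readings $M^*_h, M^*_l$ at voltages
$V_h > V_l$ (conventionally 300 V and 150 V),

$$P_{ion} = \frac{1 - V_h/V_l}{M^*_h/M^*_l - V_h/V_l}.$$

Only the two ratios enter, so the electrometer's absolute sensitivity
cancels. The formula is undefined when $M^*_h/M^*_l \ge V_h/V_l$;
`compute_pion_two_voltage()` treats that as a hard error (it indicates
saturation or swapped inputs).

**Reference scale.** Raw readings are renormalized so that the
uncorrected reading for a 10×10 cm² field at the isocenter, at the
depth of dose maximum and at the high voltage, equals 100 units:
$S^* = 100\,M^*/M^*_{ref}$. Working on this scale makes calibrations
comparable across chambers and electrometers, because the same
delivered dose produces the same $S^*$ regardless of sensitivity. The
low-voltage readings are renormalized against the same high-voltage
reference; since the two-voltage formula is ratio-based this does not
affect the estimate.

**Linear calibration.** Across setups that vary the dose per pulse
(depth, distance, field size, off-axis position), `Pion` is close to
linear in the uncorrected signal:

$$P_{ion} = m S^* + b,$$

fitted per beam-energy group by `fit_pion_calibration()`. The corrected
signal is then $S = P_{ion}(S^*)\,S^* = m (S^*)^2 + b S^*$, and the
inverse (used to go from corrected tabulated functions back to raw
signals, and by the synthetic generator)

$$S^* = \frac{-b + \sqrt{b^2 + 4 m S}}{2 m}$$

is exact; `uncorrect_signal()` falls back to $S/b$ when $m = 0$ and the
package tests the round trip to $10^{-9}$ over the whole evaluation
window.

Physically the intercept should be 1 (no signal, no recombination). The
intercept is nevertheless fitted freely: published fits of this kind
report intercepts slightly off 1, and constraining it would bias the
slope. The constructor enforces only the sanity band $b \in [0.95,
1.05]$.

## Why MU rate does not matter

The monitor-unit rate changes how many pulses are delivered per second,
not the dose in each pulse, so recombination per pulse — and hence
`Pion` — should not depend on it. `mu_rate_slope_test()` checks this on
data: it fits the slope of `Pion` against MU rate and asks whether zero
lies in the 95% bootstrap interval. The package's null simulation
(`generate_mu_rate_set()`: five rates from 400 to 2400 MU/min, ten
replicates each, Gaussian noise with SD $5\times10^{-4}$) leaves zero
inside the interval in well over 90% of seeded replications, while an
injected trend of $5\times10^{-5}$ per MU/min is reliably rejected.

## Intervals: bootstrap instead of Bayesian machinery

Interval estimates for the calibration use ordinary least squares with
a seeded nonparametric bootstrap (default 2000 resamples of the
(signal, Pion) pairs, 95% percentile interval). A Bayesian fit with
vague priors gives numerically indistinguishable intervals for a
two-parameter linear model at this noise level; the bootstrap is
dependency-free and exactly reproducible from the recorded seed. Every
fitted calibration records its seed, resample count, $R^2$ and fitted
support, and the JSON serialization round-trips all of them.

The percentile interval is widened, if necessary, to include the OLS
point estimate, so the container invariant "interval contains its
estimate" holds even in pathological resampling situations.

## Correcting the dose functions

All relative dose functions are ratios of signals, so the correction is
always a *ratio of Pions* and drops out entirely when $m = 0$:

* **%dd** (`correct_pdd()`): $\%dd = 100\,S^* P_{ion}(S^*) /
  (S^*_{dmax} P_{ion}(S^*_{dmax}))$, with dmax located as the scan's
  signal maximum and both curves renormalized to their own maxima.
* **TMR** (`correct_tmr()`): the same ratio with the chamber fixed at
  the isocenter; left as a ratio in $(0, 1]$.
* **OAR** (`correct_oar()`): normalized at the central axis, whose
  signal is linearly interpolated at $x = 0$ (not taken as the profile
  maximum — on a noisy FFF cone those can differ).
* **RDF** (`correct_rdf()`): signal ratio to the 10×10 cm² field.
  Because both signals sit within roughly ±10 units of 100, the Pion
  ratio is within $\sim10^{-3}$ of unity — the correction is detectable
  but clinically negligible.

The structure of the %dd/TMR differences follows from the ratio form:
at dmax the Pion ratio is 1 and the absolute difference vanishes; at
depth the signal is small so the absolute difference is again small;
the maximum absolute change sits at an intermediate signal. The
*relative* difference, by contrast, grows monotonically with depth. For
profiles, both the central-axis and the off-axis signal shrink with
depth, so their Pions converge and the OAR correction fades — it is
largest at dmax, concentrated in the penumbra.

Difference curves report `delta_abs = f - f*` and
`delta_rel = 100 (f - f*)/f`, the denominator being the corrected
value; at the magnitudes involved the choice of denominator is below
reporting precision.

**Field width** (`field_width_50()`, `width_delta()`): the 50% isodose
crossings of a CAX-normalized profile are found by linear interpolation
between the first bracketing sample pair *moving outward from the CAX*.
Walking outward (rather than taking, say, the outermost crossing) makes
the result robust to noise re-crossings in the tail. A positive
calibration slope lowers the shoulders, so the corrected width can only
shrink; for realistic FFF calibrations the change is a few hundredths
of a millimetre — far inside any field-size QA tolerance.

## Deriving TMR from %dd

TMR is rarely measured directly; it is derived from the %dd curve by
evaluating each depth $d$ at a point $(sad + d)$ cm from the source.
`derive_tmr_from_pdd()` first anchors the scan to SAD-scale signals
(the reference convention fixes 100 units at the SAD dmax point), then
pushes both the depth point and the dmax point to the common source
distance $(sad + d)$ with the inverse-square factor
$(sad/(sad+d))^2$. The inverse square cancels in the TMR ratio — the
uncorrected result is exactly the classic %dd-to-TMR conversion — but
it does *not* cancel in the Pion evaluation, because `Pion` depends on
the signal magnitude. At 20 cm depth the calculated magnitudes are
about $0.69\times$ the measured SAD ones, so the corrected-from-derived
TMR differs (slightly, and continuously vanishing as $m \to 0$) from
the corrected-from-measured TMR. The function returns both magnitudes
so the two routes can be compared.

Scatter beyond inverse square (phantom-scatter differences between the
geometries, a few percent in practice) has no universal functional
form; a single multiplicative `scatter_factor` hook (default 1) lets
users supply their own. It cancels in the ratio and only shifts the
Pion evaluation points. The same square field size is used at depth and
at dmax; divergence-driven field growth is not modelled.

## The kQ chain

The beam-quality conversion factor $k_Q$ of absorbed-dose protocols is
indexed by %dd(10), so a correction that moves %dd(10) moves the
absolute dose calibration: $D_w = M\,k_Q\,N_{D,w}$, and the relative
change in $k_Q$ equals the relative change in dose rate. The package
interpolates $k_Q$ linearly in a user-supplied per-chamber table
(`read_kq_table_csv()`; protocol tables are copyrighted,
version-dependent content and are deliberately not shipped), takes
%dd(10) at exactly 10.0 cm by linear interpolation, and refuses to
extrapolate outside the table. Other protocol factors (polarity,
temperature-pressure, electrometer) cancel in the ratios used here and
are out of scope; `absolute_dose()` expects an already-corrected
reading.

## The synthetic beam generator

Testing needs scan sets with known ground truth, which measured data
cannot provide. The generator works backwards from a prescribed
calibration: the noiseless **corrected** dose follows a smooth beam
model, and uncorrected signals are produced by *exact algebraic
inversion* of the calibration (and, for reading pairs, of the
two-voltage formula). Generate-then-correct is therefore an identity at
zero noise, to round-off — a property the test suite checks at
$10^{-6}$ relative for %dd, OAR and width, and $10^{-12}$ for the
two-voltage path.

The depth model is $(1 - e^{-\beta d})\,e^{-\mu d}$ buildup/attenuation
under inverse-square geometry; profiles are the FFF cone
$(1 - c\,|x|)$ rolled off through a Gaussian-integral penumbra centred
at the divergence-projected field edge. Defaults (`beam_preset()`):
$\mu = 0.044$ cm⁻¹, $\beta = 2.2$ cm⁻¹, cone 0.012 cm⁻¹, penumbra
$\sigma = 0.3$ cm for the high-energy preset; $\mu = 0.056$ cm⁻¹,
$\beta = 3.0$ cm⁻¹, cone 0.008 cm⁻¹, $\sigma = 0.35$ cm for the
low-energy one. The depth of maximum is computed numerically from the
shape (about 1.7 cm and 1.3 cm at 100 cm SSD). These are fixture
constants chosen to put synthetic scans in a realistic FFF signal
regime; they are not commissioning claims about any clinical machine,
and the generator deliberately omits voltage-dependent recombination
physics, detector volume averaging and pulse structure. Passing tests
on synthetic beams therefore validate the *algebra and numerics* of the
correction chain, not the linearity of `Pion` in real beams — that
premise comes from measurement.

Noise is multiplicative Gaussian on the uncorrected signals,
independent between the two voltage readings; every generator takes a
mandatory seed and is a pure function of (parameters, seed).

## Numerical choices and degenerate inputs

* Evaluation window: the calibration is evaluated linearly on
  $[0, 120]$ reference units (union of the fitted support if wider);
  beyond that a warning flags extrapolation, negative signals are an
  error. Corrections at depth and in the penumbra necessarily evaluate
  below the smallest fitted signal — that is the use case the
  signal-parameterized calibration exists for, so it is routine, not
  warned.
* `uncorrect_signal()` switches to the $S/b$ branch when
  $|m| <$ machine epsilon; the quadratic branch would lose all
  precision there.
* Grids are never resampled: corrections are pointwise, positions in
  cm, depth positive downward, crossplane signed about the CAX.
* Degenerate fits (fewer than 3 points, all-equal abscissae) and
  all-zero scans are errors, not NaNs. Bootstrap resamples that happen
  to be degenerate are dropped from the percentile computation.
* Calibrations are keyed by an energy-group label and corrections
  check it against the scan's label; pooling energy groups (e.g. two
  flattened beams whose calibrations are statistically
  indistinguishable) is done by the caller when assembling the fit
  input.

## Problem sizes used by the test suite

The suite runs entirely on synthetic data built at test time: 60-point
calibration designs on $S^* \in [5, 110]$ with noise SD 0.002,
bootstrap resample counts of 400–2000 (2000 where a single interval is
the object under test, 400–500 inside 200-replication coverage loops),
depth grids of ~140 points on $[0, 35]$ cm and profile grids at 1 mm
pitch. Coverage properties (bootstrap interval covering the generating
slope; zero being credible under the MU-rate null) are asserted at
≥ 90% over 200 seeded replications.

## Known limitations

* Linearity of `Pion` in $S^*$ is an empirical premise, good to the
  precision of two-voltage measurements over the clinical signal range;
  the package does not model Boag theory or dose-per-pulse physics and
  cannot detect curvature beyond the fitted diagnostics ($R^2$).
* Only crossplane profiles and square fields are handled; no 2-D/3-D
  reconstruction, no penumbra deconvolution, no vendor binary scan
  formats (the CSV dialect is the interchange point).
* The Jaffé-plot ($1/V$ vs $1/Q$) route to `Pion` and the polarity /
  temperature-pressure / electrometer corrections are out of scope.
* The kQ chain is only as good as the user-supplied table; the package
  refuses to extrapolate it.
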