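---
title: "Models and methods in quenchbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in quenchbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

quenchbind implements the analysis chain used to characterize how a small
molecule inhibits and binds an enzyme when the evidence is intrinsic protein
fluorescence plus a chromogenic activity assay. This vignette explains each
model, its assumptions, the tunable parameters, and the numerical and design
choices made where the literature leaves them open.

## 1. Inhibition assay and IC50

The activity readout is an endpoint absorbance: `a0` without inhibitor, `a1`
with. Inhibition is `S = (a0 - a1)/a0 * 100` (%), scale-invariant in the
absorbances. Negative values (apparent activation) are passed through and
counted rather than clipped, because truncation would bias downstream fits.

The IC50 is the midpoint of a four-parameter logistic (4PL)

$$S(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
        {1 + (IC_{50}/c)^h},$$

fitted by bounded least squares with `bottom` in [-10, 50] (%), `top` in
[50, 110] (%), `h > 0`. The bounds keep the plateaus physically meaningful
(small assay drift below 0% or above 100% is tolerated) while forcing the
midpoint parameter to be the 50% crossing. The optimizer is L-BFGS-B on
`(bottom, top, log10 IC50, log h)` from three Hill-slope starts, followed by
a bounded Gauss-Newton (`nls`, port algorithm) polish; the quasi-Newton
solution alone is accurate to only about 1e-5 relative in the parameters,
and the polish takes noiseless round-trips to machine precision. Replicate
wells at the same concentration are averaged before fitting, with the
per-concentration SD kept in the diagnostics. A model-free log-linear
interpolation of the 50% crossing is available as a cross-check, and a
case-resampling bootstrap (fixed seed) gives a percentile CI.

The half-maximal reference value used throughout the tests, 27.57 µg/mL, is
a *recovery* target: the generator plants it (hill 1.5, bottom 0, top 100,
10–100 µg/mL ladder) and the fitter must return it — exactly at zero noise,
and within 5% in the median over 200 seeded replicates at 2% additive
absorbance noise. No claim is made about reproducing any laboratory curve.

## 2. Inner-filter correction

Measured fluorescence is attenuated when the solution absorbs at the
excitation or emission wavelength. The multiplicative correction

$$F = F_{\mathrm{init}} \cdot e^{(A_{ex} + A_{em})/2}$$

is applied with base *e* by default; much of the wider literature uses base
10, so `correct_inner_filter(..., base = 10)` is provided as an escape
hatch. The correction is exactly multiplicative and invertible, which the
property tests exercise. Both absorbances must be present; they are part of
the spectrum metadata, not re-derived.

## 3. Stern–Volmer analysis and mechanism call

For a single quenching process, `F0/F = 1 + K_SV [Q] = 1 + K_q tau0 [Q]`.
`fit_stern_volmer` is an ordinary least-squares line of `F0/F` on `[Q]`.
The intercept is *free* by default and reported as a diagnostic: theory
forces it to 1, and how far the fitted intercept sits from 1 is useful
lack-of-fit evidence; `intercept_mode = "fixed-at-1"` constrains it. No
automatic nonlinearity rejection is performed — `r2` is reported and the
judgement left to the analyst, matching field practice.

The mechanism call divides `K_q = K_SV / tau0` (default lifetime
`tau0 = 1e-8` s, the conventional average for proteins) by the maximum
diffusion-limited collisional rate, 2.0e10 L/(mol s): strictly above is
*static-consistent* (ground-state complex), at or below *dynamic-consistent*.
The boundary is classified dynamic because only an excess over the
collisional ceiling is positive evidence for a complex.

F is read, by default, at the wavelength of the zero-quencher peak rather
than at each spectrum's own maximum: titrations often shift the band (e.g.
338 to 336 nm), and reading drifting maxima would conflate the shift with
the quench. The policy is switchable (`peak_policy = "per-spectrum"`).

## 4. Double-logarithmic binding fit

For static quenching,

$$\lg\frac{F_0 - F}{F} = \lg K_A + n \,\lg [Q],$$

so an OLS line in the double-log plane yields `lg K_A` (intercept) and the
binding-site number `n` (slope). Rows with `[Q] = 0` or `F >= F0` cannot
enter this plane (log of a non-positive number) and are excluded with a
warning count; they stay in the `F0/F` column. Because both coordinates are
ratios, the fit is invariant to uniform intensity rescaling — a property
test. K_A is reported in L/mol (the unit dimensional analysis gives for
n = 1), even though parts of the literature print L/(mol s) for it.

**Noise sensitivity.** The stability regression test adds Gaussian noise
directly to the tabulated intensities F (1% of F0) and requires the median
`p_ka` over 200 seeded replicates to stay within 0.02 of truth; it passes
with a margin. A harsher protocol — iid noise on every grid point of every
spectrum, with F0 then read at the noisy argmax of the reference — fails
that bound (median bias ≈ 0.18): the maximum of ~150 noisy points
overestimates F0 by roughly 2.5 noise SDs, and the double-log intercept,
extrapolated to `lg[Q] = 0` from data at `lg[Q] ≈ -5…-4`, amplifies the
resulting curvature. This is a real instrument-analysis caveat: F0 should
come from a smoothed or replicated reference read, not a raw grid maximum.

## 5. Van't Hoff thermodynamics

With K_A at two or more temperatures, `ln K_A = -dH/(R T) + dS/R`
(R = 8.314 J/(mol K)) is fitted by OLS in `1/T`; with exactly two
temperatures this *is* the closed-form two-point solution, which the tests
check to machine precision. `dG = dH - T dS` follows at each input
temperature, and the driving force is classified by the standard sign rules
(dH<0 & dS<0: hydrogen bonds + van der Waals; dH>0 & dS>0: hydrophobic;
dH<0 & dS>0: electrostatic). The dH>0 & dS<0 quadrant is not covered by
those rules and is deliberately labelled *indeterminate* rather than given
an invented class; values within `zero_tol` of zero likewise.

Temperatures follow the integer-Kelvin convention common in this assay
literature (30 °C -> 303 K via `+273`), because that is the convention under
which published parameter chains reproduce; `celsius_to_kelvin(x, 273.15)`
gives the exact conversion. The Van't Hoff line assumes dH constant over the
(narrow, 7 K) temperature window; no heat-capacity term is modelled.

## 6. Synchronous and 3D fluorescence

Synchronous scans with offset 15 nm report tyrosine microenvironments and
60 nm tryptophan. `residue_quench_comparison` computes the fractional peak
decline `1 - F_last/F0` per channel: a strictly deeper decline at 60 nm
labels the binding site *tryptophan-proximal*, a shallower one
*tyrosine-proximal*, equality within a relative tolerance (default 1e-9)
*indeterminate*.

`find_eem_peaks` detects 8-neighborhood local maxima of the
excitation x emission matrix after masking the first-order Rayleigh ridge
(|em - ex| < half-width) and its second order (|em - 2ex| < half-width).
The half-width default (15 nm) is conventional EEM practice and
configurable, as is the prominence threshold (default 10% of the unmasked
global maximum — the literature gives no threshold for calling the weaker
peptide-backbone peak, so it is exposed rather than hard-coded). Scatter
modelling (Raman, PARAFAC) is out of scope. Note one consequence of
masking: a band *centered* on a ridge can still leak tails past the mask
edge, and if nothing brighter exists those tails are, correctly, the most
prominent unmasked maxima. The tests therefore always plant a genuine peak
alongside a ridge peak when asserting mask behaviour.

Peak location breaks ties toward the lowest wavelength (deterministic and
order-independent), and optional smoothing is a centered moving quadratic
(Savitzky-Golay) fit, default *off* since instrument workflows in this
assay class typically report raw maxima; the reported peak intensity is
always the raw value at the chosen wavelength.

## 7. Synthetic data: the stated world

The generators produce data with exactly the structure the analyses assume:

* `simulate_titration_series` inverts the double-log law,
  `F = F0/(1 + K_A [Q]^n)`, as the *exact* generative rule — not a mixed
  static/dynamic kinetic scheme — so generator/fitter closure is exact at
  zero noise. Defaults: `p_ka = 6.7420`, `n = 1.4409`, `F0 = 642.644` a.u.,
  band center 338 nm with Gaussian sigma 25 nm on a 300–450 nm grid,
  excitation 280 nm, ladder `c(0, 3, 6, 12, 25, 50, 100)` µM (a 0–100 µM
  titration whose middle level is 12 µM; the exact ladder is not fixed by
  the source assay description, so it is a parameter). Optional inner-filter
  attenuation applies `exp(-(a_ex+a_em)/2)` so the correction recovers the
  clean series exactly.
* `simulate_ka_by_temperature` is the exact forward Van't Hoff law.
* `simulate_synchronous_pair` imposes linear-in-[Q] fractional intensity
  decline and center drift per channel (defaults: tyrosine channel at
  293 nm, fraction 0.4, −2 nm drift; tryptophan channel at 285 nm, fraction
  0.6, no drift).
* `simulate_eem` sums 2D Gaussians (defaults at (ex 280, em 338) and
  (ex 226, em 338), the aromatic-residue and peptide-backbone bands).
* `simulate_dose_response` is the forward 4PL with `a0 = 1`.

Noise is additive Gaussian on intensities, parameterized as a fraction of
the unquenched signal, clipped at zero — the simplest model consistent with
fluorimeter readouts at these intensity scales. Real spectra differ in ways
the generators deliberately omit: photobleaching and lamp drift, correlated
(non-iid) noise, Raman scatter, non-Gaussian band shapes, and titration
dilution effects. A green closure test therefore establishes that the
estimators invert their models correctly and are stable to benign noise —
not that any laboratory system obeys those models.

## 8. Reproducibility and I/O

All randomness flows through explicit seeds (`with_seed` restores the
caller's RNG state). CSV writers emit 17 significant digits so read-backs
are bit-exact; `report.json` is written with full precision (`digits = NA`)
and reruns of the same configuration are byte-identical. The CSV dialect is
fixed (comma separator, `.` decimal, `#`-prefixed `key: value` metadata
lines) for cross-locale safety, concentrations are kept in the units the
assays use (mol/L for binding, µg/mL mass concentration for dose–response —
no silent molar-mass conversion), and wavelength grids within a series must
match exactly: resampling would smuggle in an interpolation model the
analysis never states.

## 9. Known limitations

* Only the simple Stern–Volmer model is implemented — no modified
  (Lineweaver-type) or combined static+dynamic variants.
* No mode-of-inhibition kinetics (Lineweaver–Burk, K_i).
* The pipeline ingests titration and dose–response tables from CSV;
  synchronous series and EEMs enter as in-memory objects.
* The EEM peak finder reports grid-resolution positions (no sub-grid
  interpolation).
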