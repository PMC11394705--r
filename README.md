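# quenchbind

Analysis toolkit for protein–ligand interaction studies that combine an
enzyme-inhibition assay with intrinsic-fluorescence spectroscopy — the
standard workflow used to characterize natural enzyme inhibitors (e.g. a
flavonoid binding α-glucosidase). It is aimed at researchers who have
titration spectra, synchronous scans, excitation–emission matrices (EEMs)
and chromogenic dose–response readings and want the full chain of derived
quantities with a reproducible, scriptable pipeline.

## What it computes

* **Inhibition and IC50.** Inhibition percentage `S = (A0 − A1)/A0 × 100`
  from control/sample absorbances, and the half-inhibitory concentration
  from a four-parameter logistic
  `S = bottom + (top − bottom) / (1 + (IC50/c)^h)` fitted by bounded least
  squares (`bottom ∈ [−10, 50]`, `top ∈ [50, 110]`, `h > 0`), with a
  model-free log-linear interpolation cross-check and an optional bootstrap
  confidence interval.
* **Inner-filter correction.** `F = F_init · e^((A_ex + A_em)/2)` (base-10
  variant available).
* **Stern–Volmer analysis.** OLS of `F0/F = 1 + K_SV[Q]`; the quenching rate
  constant `K_q = K_SV/τ0` (default τ0 = 10⁻⁸ s) is compared with the
  diffusion-limited collisional maximum 2.0 × 10¹⁰ L/(mol·s): larger is
  consistent with static quenching (ground-state complex), smaller with
  dynamic (collisional) quenching.
* **Double-logarithmic (Hill-type) binding fit.**
  `lg((F0 − F)/F) = lg K_A + n·lg[Q]` giving the binding constant K_A
  (L/mol) and binding-site number n.
* **Van't Hoff thermodynamics.** `ln K_A = −ΔH/(RT) + ΔS/R`
  (R = 8.314 J mol⁻¹ K⁻¹), `ΔG = ΔH − TΔS`, and the sign-rule driving-force
  classification (ΔH<0, ΔS<0 → hydrogen bonds + van der Waals; ΔH>0, ΔS>0 →
  hydrophobic; ΔH<0, ΔS>0 → electrostatic).
* **Conformational probes.** Emission-peak location and blue/red shift
  tracking, tyrosine (Δλ = 15 nm) vs tryptophan (Δλ = 60 nm) synchronous
  quench-depth comparison, and EEM peak detection with Rayleigh first/second
  order scatter masking.
* **Synthetic data.** Every stage has a ground-truth generator
  (`simulate_*`), so the whole pipeline is testable without instrument data.

## Worked example

```r
library(quenchbind)

# A titration with known truth: pK_A = 6.7420, n = 1.4409, 0-100 uM ladder
ser <- simulate_titration_series(p_ka = 6.7420, n = 1.4409)
qt  <- build_quench_table(ser)
fit_stern_volmer(qt)
#> <stern_volmer_fit> K_SV = 95319.3 L/mol, K_q = 9.53193e+12 L/(mol s), intercept = 0.4717, r2 = 0.9789, static-consistent
fit_double_log(qt)
#> <double_log_fit> pK_A = 6.7420 (K_A = 5.521e+06 L/mol), n = 1.4409, r2 = 1.0000 (6 points)

# Thermodynamics from binding constants at 30 and 37 C
thermo_analysis(c("303" = 10^6.7420, "310" = 10^4.2702))
#> <thermo_result> dH = -634.96 kJ/mol, dS = -1966.51 J/(mol K), force: hydrogen-bond+van-der-Waals
#>   dG(303 K) = -39.11 kJ/mol
#>   dG(310 K) = -25.34 kJ/mol

# IC50 from a dose-response table
fit_ic50(simulate_dose_response(ic50 = 27.57, hill = 1.5))
#> <inhibition_curve> four-parameter-logistic: IC50 = 27.57 ug/mL, 10 concentrations

# Peak drift across a titration (negative = blue shift)
peak_shift_series(simulate_titration_series(peak_drift_nm = -2))
#> <shift_result> 338 -> 336 nm (shift -2 nm, blue)
```

Reading the output: the double-log fit recovers the generating binding
constant exactly (K_A ≈ 5.52 × 10⁶ L/mol, n ≈ 1.44). The Stern–Volmer K_q
(~10¹³ L mol⁻¹ s⁻¹) is far above the 2 × 10¹⁰ collisional ceiling, so the
quenching is static — note its r² < 1 and intercept ≠ 1 are expected here,
since an n ≠ 1 binding law makes F0/F nonlinear in [Q]. Both ΔH and ΔS are
negative, so hydrogen bonding and van der Waals contacts dominate and the
negative ΔG values mark spontaneous binding. The simulated 2 nm blue shift
is recovered as written.

## Pipeline and CLI

`run_pipeline(config, out = dir)` executes whichever stages have inputs
(dose–response CSV, per-temperature titration CSVs, binding constants,
synchronous pairs, an EEM) and writes `report.json` plus flat CSV tables;
reruns are byte-identical. A thin command-line front end lives at
`inst/cli/quenchbind.R`:

```sh
Rscript inst/cli/quenchbind.R run    --config pipeline.cfg --out results/
Rscript inst/cli/quenchbind.R thermo --ka "303=5.52e6,310=1.86e4"
Rscript inst/cli/quenchbind.R ic50   --input dose.csv
```

## Layout

* `R/` — data model + I/O, spectral preprocessing, binding analysis,
  thermodynamics, inhibition assay, synthetic generators, pipeline.
* `tests/testthat/` — unit, property and acceptance tests.
* `vignettes/quenchbind-methods.Rmd` — models, assumptions, numerical
  choices and limitations.
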