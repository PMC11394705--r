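# Synthetic-data generators with known ground truth. Every generator is
# deterministic under a fixed seed; noise is additive Gaussian on intensities,
# parameterized as a fraction of the unquenched signal, and results are
# clipped at zero (intensities are physically non-negative).

#' Simulate a static-quenching titration series
#'
#' Forward model of a tryptophan/tyrosine emission band quenched by
#' ground-state complex formation. For each quencher concentration `[Q] > 0`
#' the peak intensity obeys the double-log binding law exactly before noise:
#' `F = F0 / (1 + K_A [Q]^n)` with `K_A = 10^p_ka`, i.e.
#' `lg((F0 - F)/F) = p_ka + n lg[Q]`. The band is Gaussian with its center
#' drifting linearly in `[Q]` up to `peak_drift_nm` at the top concentration.
#' If absorbance schedules are given, the emitted (raw) intensities are
#' attenuated by `exp(-(a_ex + a_em)/2)` so that [correct_inner_filter()]
#' (base e) recovers the clean series exactly.
#'
#' @param p_ka log10 binding constant; default 6.7420.
#' @param n Binding-site number; default 1.4409.
#' @param f0_peak_au Unquenched peak height; default 642.644.
#' @param peak_center_nm Band center at `[Q] = 0`; default 338.
#' @param peak_width_nm Gaussian sigma of the band (nm); default 25.
#' @param peak_drift_nm Total center drift at the top concentration (negative
#'   = blue shift); default 0.
#' @param conc_ladder_M Quencher ladder (mol/L), starting at 0 and strictly
#'   increasing; default `c(0, 3, 6, 12, 25, 50, 100) * 1e-6` (a 0-100 uM
#'   titration with 12 uM as the intermediate level).
#' @param a_ex,a_em Optional per-concentration absorbance schedules (same
#'   length as the ladder); default all zero.
#' @param noise_sd_fraction SD of the additive Gaussian noise as a fraction of
#'   `f0_peak_au`; default 0.
#' @param seed RNG seed for the noise.
#' @param excitation_nm,temperature_K Scan metadata; defaults 280 nm, 303 K.
#' @param wavelengths_nm Emission grid; default `seq(300, 450, by = 1)`.
#' @return A [titration_series()].
#' @export
simulate_titration_series <- function(p_ka = 6.7420, n = 1.4409,
                                      f0_peak_au = 642.644,
                                      peak_center_nm = 338,
                                      peak_width_nm = 25,
                                      peak_drift_nm = 0,
                                      conc_ladder_M = c(0, 3, 6, 12, 25, 50, 100) * 1e-6,
                                      a_ex = NULL, a_em = NULL,
                                      noise_sd_fraction = 0,
                                      seed = NULL,
                                      excitation_nm = 280,
                                      temperature_K = 303,
                                      wavelengths_nm = seq(300, 450, by = 1)) {
  if (length(conc_ladder_M) < 2L || conc_ladder_M[1] != 0) {
    validation_error("conc_ladder_M must start at 0")
  }
  if (!is_strictly_increasing(conc_ladder_M)) {
    validation_error("conc_ladder_M must be strictly increasing")
  }
  if (!is.finite(n) || n <= 0) validation_error("n must be > 0")
  if (noise_sd_fraction < 0) validation_error("noise_sd_fraction must be >= 0")
  nq <- length(conc_ladder_M)
  if (is.null(a_ex)) a_ex <- rep(0, nq)
  if (is.null(a_em)) a_em <- rep(0, nq)
  if (length(a_ex) != nq || length(a_em) != nq) {
    validation_error("a_ex/a_em schedules must match the ladder length")
  }
  ka <- 10^p_ka
  qmax <- max(conc_ladder_M)
  with_seed(seed, {
    spectra <- lapply(seq_len(nq), function(i) {
      q <- conc_ladder_M[i]
      f_peak <- if (q == 0) f0_peak_au else f0_peak_au / (1 + ka * q^n)
      center <- peak_center_nm + peak_drift_nm * q / qmax
      clean <- f_peak * exp(-0.5 * ((wavelengths_nm - center) / peak_width_nm)^2)
      raw <- clean * exp(-(a_ex[i] + a_em[i]) / 2)
      if (noise_sd_fraction > 0) {
        raw <- raw + stats::rnorm(length(raw), sd = noise_sd_fraction * f0_peak_au)
        raw <- pmax(raw, 0)
      }
      emission_spectrum(
        wavelengths_nm = wavelengths_nm,
        intensities_au = raw,
        excitation_nm = excitation_nm,
        temperature_K = temperature_K,
        quencher_conc_M = q,
        a_ex = a_ex[i],
        a_em = a_em[i]
      )
    })
    titration_series(spectra)
  })
}

#' Simulate binding constants across temperatures
#'
#' Forward Van't Hoff model: `K_A(T) = exp(-dH/(R T) + dS/R)` exactly, with
#' R = 8.314 J/(mol K).
#'
#' @param delta_h_J_mol Enthalpy change (J/mol).
#' @param delta_s_J_molK Entropy change (J/(mol K)).
#' @param temperatures_K Temperatures (K), > 0, >= 2 of them.
#' @return Named numeric vector of binding constants (names = temperatures).
#' @export
simulate_ka_by_temperature <- function(delta_h_J_mol, delta_s_J_molK,
                                       temperatures_K) {
  if (length(temperatures_K) < 2L) precondition_error("need >= 2 temperatures")
  if (any(temperatures_K <= 0)) validation_error("temperatures must be > 0 K")
  ka <- exp(-delta_h_J_mol / (R_GAS * temperatures_K) + delta_s_J_molK / R_GAS)
  names(ka) <- as.character(temperatures_K)
  ka
}

sim_sync_series <- function(truth, conc_ladder_M, temperature_K, noise_sd_fraction) {
  grid <- truth$excitation_grid_nm
  qmax <- max(conc_ladder_M)
  lapply(seq_along(conc_ladder_M), function(i) {
    q <- conc_ladder_M[i]
    scale <- truth$f0_au * (1 - truth$quench_fraction * q / qmax)
    center <- truth$center_nm + truth$drift_nm * q / qmax
    au <- scale * exp(-0.5 * ((grid - center) / truth$width_nm)^2)
    if (noise_sd_fraction > 0) {
      au <- pmax(au + stats::rnorm(length(au), sd = noise_sd_fraction * truth$f0_au), 0)
    }
    synchronous_spectrum(grid, au, truth$delta_lambda_nm, q, temperature_K)
  })
}

#' Simulate a pair of synchronous titration series
#'
#' Two synchronous channels over the same concentration ladder: delta-lambda
#' 15 nm (tyrosine) and 60 nm (tryptophan). Each channel's peak intensity
#' declines linearly in `[Q]` to the stated `quench_fraction` at the top
#' concentration, and its Gaussian band center drifts linearly by `drift_nm`,
#' so [residue_quench_comparison()] and [peak_shift_series()] recover the
#' truths exactly at zero noise.
#'
#' @param truth15,truth60 Named lists with fields `center_nm`, `width_nm`,
#'   `f0_au`, `quench_fraction` (total fractional decline in `[0, 1)`),
#'   `drift_nm`, `delta_lambda_nm`, `excitation_grid_nm`. Defaults emulate a
#'   tyrosine channel at 293 nm (fraction 0.4, -2 nm drift) and a tryptophan
#'   channel at 285 nm (fraction 0.6, no drift).
#' @param conc_ladder_M Shared concentration ladder (mol/L), default as in
#'   [simulate_titration_series()].
#' @param temperature_K Temperature (K); default 303.
#' @param noise_sd_fraction Additive noise SD as a fraction of each channel's
#'   `f0_au`; default 0.
#' @param seed RNG seed.
#' @return A list with elements `series15` and `series60`, each a list of
#'   [synchronous_spectrum()] objects.
#' @export
simulate_synchronous_pair <- function(
    truth15 = list(center_nm = 293, width_nm = 12, f0_au = 400,
                   quench_fraction = 0.4, drift_nm = -2,
                   delta_lambda_nm = 15,
                   excitation_grid_nm = seq(265, 350, by = 1)),
    truth60 = list(center_nm = 285, width_nm = 12, f0_au = 600,
                   quench_fraction = 0.6, drift_nm = 0,
                   delta_lambda_nm = 60,
                   excitation_grid_nm = seq(220, 350, by = 1)),
    conc_ladder_M = c(0, 3, 6, 12, 25, 50, 100) * 1e-6,
    temperature_K = 303,
    noise_sd_fraction = 0,
    seed = NULL) {
  if (conc_ladder_M[1] != 0 || !is_strictly_increasing(conc_ladder_M)) {
    validation_error("conc_ladder_M must start at 0 and strictly increase")
  }
  for (tr in list(truth15, truth60)) {
    if (tr$quench_fraction < 0 || tr$quench_fraction >= 1) {
      validation_error("quench_fraction must be in [0, 1)")
    }
  }
  with_seed(seed, {
    list(
      series15 = sim_sync_series(truth15, conc_ladder_M, temperature_K, noise_sd_fraction),
      series60 = sim_sync_series(truth60, conc_ladder_M, temperature_K, noise_sd_fraction)
    )
  })
}

#' Simulate an excitation-emission matrix
#'
#' Sum of 2D Gaussian peaks on an excitation x emission grid. The defaults
#' place the two bands typical of a protein EEM: the aromatic-residue band
#' (ex 280 / em 338 nm) and the peptide-backbone band (ex 226 / em 338 nm).
#'
#' @param peaks Data.frame with columns `excitation_nm`, `emission_nm`,
#'   `height_au`.
#' @param excitation_grid_nm,emission_grid_nm Grids; defaults 220-300 and
#'   300-450 nm in 2 nm steps.
#' @param width_ex_nm,width_em_nm Gaussian sigmas; defaults 10 and 15 nm.
#' @param quencher_conc_M Metadata; default 0.
#' @param noise_sd_au Additive Gaussian noise SD (a.u.); default 0.
#' @param seed RNG seed.
#' @return An [eem()].
#' @export
simulate_eem <- function(peaks = data.frame(excitation_nm = c(280, 226),
                                            emission_nm = c(338, 338),
                                            height_au = c(1000, 800)),
                         excitation_grid_nm = seq(220, 300, by = 2),
                         emission_grid_nm = seq(300, 450, by = 2),
                         width_ex_nm = 10, width_em_nm = 15,
                         quencher_conc_M = 0,
                         noise_sd_au = 0, seed = NULL) {
  m <- matrix(0, length(excitation_grid_nm), length(emission_grid_nm))
  for (k in seq_len(nrow(peaks))) {
    gx <- exp(-0.5 * ((excitation_grid_nm - peaks$excitation_nm[k]) / width_ex_nm)^2)
    gm <- exp(-0.5 * ((emission_grid_nm - peaks$emission_nm[k]) / width_em_nm)^2)
    m <- m + peaks$height_au[k] * outer(gx, gm)
  }
  with_seed(seed, {
    if (noise_sd_au > 0) {
      m <- pmax(m + stats::rnorm(length(m), sd = noise_sd_au), 0)
    }
    eem(excitation_grid_nm, emission_grid_nm, m, quencher_conc_M)
  })
}

#' Simulate a dose-response absorbance table
#'
#' Forward four-parameter logistic: the control absorbance is fixed at 1.0
#' and the sample absorbance is `a1 = a0 (1 - S/100)` with
#' `S = bottom + (top - bottom)/(1 + (IC50/c)^h)`. Optional seeded additive
#' Gaussian noise on `a1` (clipped at 0).
#'
#' @param ic50 Half-inhibitory concentration (ug/mL); default 27.57.
#' @param hill Hill slope; default 1.5.
#' @param bottom,top Lower/upper inhibition plateaus (percent); defaults 0, 100.
#' @param conc_ladder Concentrations (ug/mL), positive increasing; default
#'   `seq(10, 100, by = 10)`.
#' @param noise_sd_pct Noise SD on `a1`, percent of `a0`; default 0.
#' @param seed RNG seed.
#' @return A [dose_response_table()].
#' @export
simulate_dose_response <- function(ic50 = 27.57, hill = 1.5, bottom = 0,
                                   top = 100,
                                   conc_ladder = seq(10, 100, by = 10),
                                   noise_sd_pct = 0, seed = NULL) {
  if (ic50 <= 0) validation_error("ic50 must be > 0")
  if (any(conc_ladder <= 0) || !is_strictly_increasing(conc_ladder)) {
    validation_error("conc_ladder must be positive and strictly increasing")
  }
  s <- four_pl(conc_ladder, bottom, top, ic50, hill)
  a0 <- rep(1, length(conc_ladder))
  a1 <- a0 * (1 - s / 100)
  with_seed(seed, {
    if (noise_sd_pct > 0) {
      a1 <- pmax(a1 + stats::rnorm(length(a1), sd = noise_sd_pct / 100), 0)
    }
    dose_response_table(conc_ladder, a0, a1)
  })
}
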