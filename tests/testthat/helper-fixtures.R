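# Shared fixtures, built in code.

gaussian_spectrum <- function(center = 338, height = 600, sigma = 25,
                              wl = seq(300, 450, by = 1), conc = 0,
                              a_ex = 0, a_em = 0, temperature_K = 303) {
  emission_spectrum(
    wavelengths_nm = wl,
    intensities_au = height * exp(-0.5 * ((wl - center) / sigma)^2),
    excitation_nm = 280,
    temperature_K = temperature_K,
    quencher_conc_M = conc,
    a_ex = a_ex, a_em = a_em
  )
}

# Exact Stern-Volmer line F0/F = 1 + k_sv [Q] turned into a series of flat-top
# "spectra" (single Gaussian, peak scaled), bypassing the generator.
sv_series <- function(k_sv = 43541, conc = c(0, 1e-5, 2e-5, 4e-5, 8e-5),
                      f0 = 642.644) {
  spectra <- lapply(conc, function(q) {
    gaussian_spectrum(height = f0 / (1 + k_sv * q), conc = q)
  })
  titration_series(spectra)
}

table1_ka <- c("303" = 10^6.7420, "310" = 10^4.2702)
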