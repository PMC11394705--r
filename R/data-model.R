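#' Construct a single emission spectrum
#'
#' An emission spectrum is one fluorimeter scan of the protein solution at a
#' fixed excitation wavelength, temperature and quencher (ligand)
#' concentration. Optional absorbances at the excitation and emission
#' wavelengths (`a_ex`, `a_em`) enable inner-filter-effect correction.
#'
#' @param wavelengths_nm Strictly increasing emission wavelengths (nm).
#' @param intensities_au Fluorescence intensities (arbitrary units), finite
#'   and non-negative, same length as `wavelengths_nm`.
#' @param excitation_nm Excitation wavelength (nm).
#' @param temperature_K Absolute temperature (K), > 0.
#' @param quencher_conc_M Quencher concentration `[Q]` in mol/L, >= 0.
#' @param a_ex,a_em Optional absorbances at excitation/emission wavelength
#'   (dimensionless, >= 0).
#' @param corrected Logical flag: has the inner-filter correction been applied?
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelengths_nm, intensities_au, excitation_nm,
                              temperature_K, quencher_conc_M,
                              a_ex = NULL, a_em = NULL, corrected = FALSE) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  intensities_au <- as.numeric(intensities_au)
  if (length(wavelengths_nm) != length(intensities_au)) {
    validation_error("wavelengths and intensities must have equal length")
  }
  if (!is_strictly_increasing(wavelengths_nm)) {
    format_error("wavelength grid must be strictly increasing")
  }
  if (anyNA(intensities_au) || any(!is.finite(intensities_au))) {
    format_error("intensities must be finite (no NA/NaN/Inf)")
  }
  if (any(intensities_au < 0)) {
    validation_error("intensities must be non-negative")
  }
  if (!is.finite(temperature_K) || temperature_K <= 0) {
    validation_error("temperature_K must be > 0")
  }
  if (!is.finite(quencher_conc_M) || quencher_conc_M < 0) {
    validation_error("quencher_conc_M must be >= 0")
  }
  for (a in list(a_ex = a_ex, a_em = a_em)) {
    if (!is.null(a) && (!is.finite(a) || a < 0)) {
      validation_error("absorbances a_ex/a_em must be finite and >= 0")
    }
  }
  structure(
    list(
      wavelengths_nm = wavelengths_nm,
      intensities_au = intensities_au,
      excitation_nm = as.numeric(excitation_nm),
      temperature_K = as.numeric(temperature_K),
      quencher_conc_M = as.numeric(quencher_conc_M),
      a_ex = if (is.null(a_ex)) NULL else as.numeric(a_ex),
      a_em = if (is.null(a_em)) NULL else as.numeric(a_em),
      corrected = isTRUE(corrected)
    ),
    class = "emission_spectrum"
  )
}

#' Construct a quenching titration series
#'
#' A titration series collects emission spectra of one protein preparation at
#' increasing quencher concentrations, at one temperature and excitation
#' wavelength. The first spectrum must be the quencher-free reference (it
#' defines F0); all spectra must share the wavelength grid exactly.
#'
#' @param spectra List of [emission_spectrum()] objects, ordered by strictly
#'   increasing quencher concentration, the first at `[Q] = 0`.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(spectra) {
  if (length(spectra) < 2L) {
    validation_error("a titration series needs at least 2 spectra")
  }
  if (!all(vapply(spectra, inherits, logical(1), "emission_spectrum"))) {
    validation_error("all elements must be emission_spectrum objects")
  }
  conc <- vapply(spectra, `[[`, numeric(1), "quencher_conc_M")
  if (conc[1] != 0) {
    format_error("no F0 reference: first spectrum must have quencher_conc_M = 0")
  }
  if (!is_strictly_increasing(conc)) {
    validation_error("quencher concentrations must be strictly increasing")
  }
  grid <- spectra[[1]]$wavelengths_nm
  same_grid <- vapply(spectra, function(s) {
    length(s$wavelengths_nm) == length(grid) && all(s$wavelengths_nm == grid)
  }, logical(1))
  if (!all(same_grid)) {
    validation_error("all spectra must share the wavelength grid exactly")
  }
  ex <- vapply(spectra, `[[`, numeric(1), "excitation_nm")
  tk <- vapply(spectra, `[[`, numeric(1), "temperature_K")
  if (length(unique(ex)) != 1L || length(unique(tk)) != 1L) {
    validation_error("all spectra must share excitation_nm and temperature_K")
  }
  structure(
    list(
      spectra = spectra,
      excitation_nm = ex[1],
      temperature_K = tk[1],
      quencher_conc_M = conc,
      wavelengths_nm = grid
    ),
    class = "titration_series"
  )
}

#' Construct a synchronous-scan spectrum
#'
#' A synchronous scan sweeps excitation and emission together with a fixed
#' offset delta-lambda; 15 nm probes tyrosine and 60 nm tryptophan
#' microenvironments.
#'
#' @param excitation_nm Strictly increasing excitation wavelengths (nm).
#' @param intensities_au Intensities (a.u.), same length.
#' @param delta_lambda_nm Fixed emission-excitation offset (> 0), typically 15 or 60.
#' @param quencher_conc_M Quencher concentration (mol/L).
#' @param temperature_K Absolute temperature (K).
#' @return An object of class `synchronous_spectrum`.
#' @export
synchronous_spectrum <- function(excitation_nm, intensities_au, delta_lambda_nm,
                                 quencher_conc_M, temperature_K) {
  excitation_nm <- as.numeric(excitation_nm)
  intensities_au <- as.numeric(intensities_au)
  if (length(excitation_nm) != length(intensities_au)) {
    validation_error("excitation grid and intensities must have equal length")
  }
  if (!is_strictly_increasing(excitation_nm)) {
    format_error("excitation grid must be strictly increasing")
  }
  if (!is.finite(delta_lambda_nm) || delta_lambda_nm <= 0) {
    validation_error("delta_lambda_nm must be > 0")
  }
  if (any(!is.finite(intensities_au)) || any(intensities_au < 0)) {
    validation_error("intensities must be finite and non-negative")
  }
  structure(
    list(
      excitation_nm = excitation_nm,
      intensities_au = intensities_au,
      delta_lambda_nm = as.numeric(delta_lambda_nm),
      quencher_conc_M = as.numeric(quencher_conc_M),
      temperature_K = as.numeric(temperature_K)
    ),
    class = "synchronous_spectrum"
  )
}

#' Construct an excitation-emission matrix (EEM)
#'
#' @param excitation_grid_nm,emission_grid_nm Strictly increasing wavelength grids.
#' @param intensity_matrix Matrix of intensities (rows = excitation, columns =
#'   emission), all >= 0.
#' @param quencher_conc_M Quencher concentration (mol/L).
#' @return An object of class `eem`.
#' @export
eem <- function(excitation_grid_nm, emission_grid_nm, intensity_matrix,
                quencher_conc_M = 0) {
  excitation_grid_nm <- as.numeric(excitation_grid_nm)
  emission_grid_nm <- as.numeric(emission_grid_nm)
  if (!is_strictly_increasing(excitation_grid_nm) ||
      !is_strictly_increasing(emission_grid_nm)) {
    format_error("EEM grids must be strictly increasing")
  }
  intensity_matrix <- as.matrix(intensity_matrix)
  if (nrow(intensity_matrix) != length(excitation_grid_nm) ||
      ncol(intensity_matrix) != length(emission_grid_nm)) {
    validation_error("intensity matrix dimensions must match the grids")
  }
  if (any(!is.finite(intensity_matrix)) || any(intensity_matrix < 0)) {
    validation_error("EEM intensities must be finite and non-negative")
  }
  structure(
    list(
      excitation_grid_nm = excitation_grid_nm,
      emission_grid_nm = emission_grid_nm,
      intensity_matrix = intensity_matrix,
      quencher_conc_M = as.numeric(quencher_conc_M)
    ),
    class = "eem"
  )
}

#' Construct a dose-response table
#'
#' Rows pair an inhibitor concentration (mass concentration, ug/mL) with the
#' control absorbance `a0` (no inhibitor) and sample absorbance `a1`. Rows are
#' sorted by concentration.
#'
#' @param conc_ug_ml Inhibitor concentrations (ug/mL), > 0, no duplicates.
#' @param a0 Control absorbances, > 0.
#' @param a1 Sample absorbances, >= 0.
#' @return A data.frame of class `dose_response_table`.
#' @export
dose_response_table <- function(conc_ug_ml, a0, a1) {
  conc_ug_ml <- as.numeric(conc_ug_ml)
  a0 <- as.numeric(a0)
  a1 <- as.numeric(a1)
  if (length(conc_ug_ml) != length(a0) || length(a0) != length(a1)) {
    validation_error("conc_ug_ml, a0 and a1 must have equal length")
  }
  if (anyNA(conc_ug_ml) || any(!is.finite(conc_ug_ml)) || any(conc_ug_ml <= 0)) {
    format_error("concentrations must be finite and > 0")
  }
  if (anyNA(a0) || any(!is.finite(a0)) || any(a0 <= 0)) {
    qb_stop("a0 must be > 0 (division guard)", "quenchbind_guard_error")
  }
  if (anyNA(a1) || any(!is.finite(a1)) || any(a1 < 0)) {
    format_error("a1 must be finite and >= 0")
  }
  ord <- order(conc_ug_ml)
  conc_ug_ml <- conc_ug_ml[ord]
  if (anyDuplicated(conc_ug_ml)) {
    format_error("concentrations must be strictly increasing (no duplicates)")
  }
  out <- data.frame(conc_ug_ml = conc_ug_ml, a0 = a0[ord], a1 = a1[ord])
  class(out) <- c("dose_response_table", "data.frame")
  out
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series> %d spectra, ex %g nm, %g K, [Q] %s mol/L\n",
    length(x$spectra), x$excitation_nm, x$temperature_K,
    paste(signif(x$quencher_conc_M, 3), collapse = ", ")
  ))
  invisible(x)
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf(
    "<emission_spectrum> %d points (%g-%g nm), ex %g nm, [Q] %g mol/L%s\n",
    length(x$wavelengths_nm), min(x$wavelengths_nm), max(x$wavelengths_nm),
    x$excitation_nm, x$quencher_conc_M,
    if (x$corrected) ", IFE-corrected" else ""
  ))
  invisible(x)
}
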