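# Spectral preprocessing: inner-filter correction, peak location and shift
# tracking, synchronous residue comparison, EEM peak detection.

#' Inner-filter-effect correction
#'
#' Re-absorption of excitation and emission light attenuates the measured
#' fluorescence. The standard multiplicative correction rescales every
#' intensity by `base^((a_ex + a_em)/2)`, using the solution absorbances at
#' the excitation and emission wavelengths. The default base is `e`; the
#' base-10 variant common in the wider literature is available via `base = 10`.
#'
#' @param spectrum An [emission_spectrum()] with `a_ex` and `a_em` present.
#' @param base Correction base, default `exp(1)`.
#' @return The corrected [emission_spectrum()], flagged `corrected = TRUE`.
#' @export
correct_inner_filter <- function(spectrum, base = exp(1)) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  if (is.null(spectrum$a_ex) || is.null(spectrum$a_em)) {
    precondition_error("a_ex and a_em are required for inner-filter correction")
  }
  if (spectrum$a_ex < 0 || spectrum$a_em < 0) {
    validation_error("absorbances must be >= 0")
  }
  factor <- base^((spectrum$a_ex + spectrum$a_em) / 2)
  out <- spectrum
  out$intensities_au <- spectrum$intensities_au * factor
  out$corrected <- TRUE
  out
}

# Wavelength axis + intensities for either spectrum flavour.
spectrum_axis <- function(x) {
  if (inherits(x, "emission_spectrum")) {
    list(nm = x$wavelengths_nm, au = x$intensities_au)
  } else if (inherits(x, "synchronous_spectrum")) {
    list(nm = x$excitation_nm, au = x$intensities_au)
  } else {
    precondition_error("expected an emission_spectrum or synchronous_spectrum")
  }
}

# Centered moving quadratic (Savitzky-Golay) smoother; window shrinks at the
# edges but always keeps >= 3 points so the local fit is determined.
quad_smooth <- function(nm, au, window) {
  if (window %% 2L != 1L || window < 3L) {
    validation_error("smoothing window must be an odd integer >= 3")
  }
  n <- length(au)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    if (hi - lo + 1L < 3L) {
      out[i] <- au[i]
      next
    }
    x <- nm[lo:hi] - nm[i]
    y <- au[lo:hi]
    fit <- stats::lm.fit(cbind(1, x, x^2), y)
    out[i] <- fit$coefficients[1]
  }
  out
}

#' Locate the emission peak of a spectrum
#'
#' Returns the grid wavelength with the highest (optionally smoothed)
#' intensity. Ties break toward the lowest wavelength, and the reported
#' intensity is always the raw (unsmoothed) value at the chosen wavelength.
#' An all-zero spectrum yields the lowest wavelength with a
#' `degenerate = TRUE` flag.
#'
#' @param spectrum An [emission_spectrum()] or [synchronous_spectrum()].
#' @param window_nm Optional `c(lo, hi)` search window (nm).
#' @param smooth Optional odd window length for a centered moving quadratic
#'   fit; default `NULL` (off).
#' @return A list of class `peak_call`: `peak_nm`, `peak_intensity_au`,
#'   `window_nm`, `degenerate`.
#' @export
locate_peak <- function(spectrum, window_nm = NULL, smooth = NULL) {
  ax <- spectrum_axis(spectrum)
  keep <- if (is.null(window_nm)) {
    rep(TRUE, length(ax$nm))
  } else {
    ax$nm >= window_nm[1] & ax$nm <= window_nm[2]
  }
  if (!any(keep)) precondition_error("empty search window")
  nm <- ax$nm[keep]
  au <- ax$au[keep]
  if (length(nm) < 3L) precondition_error("need >= 3 points in the search window")
  degenerate <- all(au == 0)
  score <- if (is.null(smooth) || degenerate) au else quad_smooth(nm, au, smooth)
  idx <- which(score == max(score))[1]  # tie -> lowest wavelength
  if (degenerate) idx <- 1L
  structure(
    list(
      peak_nm = nm[idx],
      peak_intensity_au = au[idx],
      window_nm = if (is.null(window_nm)) range(nm) else window_nm,
      degenerate = degenerate
    ),
    class = "peak_call"
  )
}

#' Peak shift across a titration
#'
#' Compares the peak of the quencher-free spectrum with the peak of the
#' highest-concentration spectrum. A negative shift is a blue shift
#' (hydrophobicity increase around the fluorophore); positive is red.
#'
#' @param series A [titration_series()] or a list of
#'   [synchronous_spectrum()] objects ordered by concentration.
#' @param window_nm,smooth Passed to [locate_peak()].
#' @return A list of class `shift_result`: `start_nm`, `end_nm`, `shift_nm`,
#'   `direction` (one of `"blue"`, `"red"`, `"none"`), `degenerate`.
#' @export
peak_shift_series <- function(series, window_nm = NULL, smooth = NULL) {
  spectra <- if (inherits(series, "titration_series")) series$spectra else series
  if (length(spectra) < 2L) precondition_error("need >= 2 spectra")
  conc <- vapply(spectra, `[[`, numeric(1), "quencher_conc_M")
  first <- spectra[[which.min(conc)]]
  last <- spectra[[which.max(conc)]]
  p0 <- locate_peak(first, window_nm = window_nm, smooth = smooth)
  p1 <- locate_peak(last, window_nm = window_nm, smooth = smooth)
  shift <- p1$peak_nm - p0$peak_nm
  structure(
    list(
      start_nm = p0$peak_nm,
      end_nm = p1$peak_nm,
      shift_nm = shift,
      direction = if (shift < 0) "blue" else if (shift > 0) "red" else "none",
      degenerate = p0$degenerate || p1$degenerate
    ),
    class = "shift_result"
  )
}

#' Compare quenching depth between tyrosine and tryptophan channels
#'
#' Synchronous scans at delta-lambda 15 nm report tyrosine residues and at
#' 60 nm tryptophan residues. The fractional peak-intensity decrease
#' `1 - F_last/F_0` in each channel indicates which residue type sits closer
#' to the binding site: a strictly larger decrease in the 60 nm channel is
#' called tryptophan-proximal, a strictly smaller one tyrosine-proximal.
#'
#' @param series15 List of [synchronous_spectrum()] at delta-lambda 15 nm,
#'   ordered by concentration.
#' @param series60 Same ladder at delta-lambda 60 nm.
#' @param tol Relative tolerance inside which the two fractions are treated
#'   as equal (label `"indeterminate"`); default `1e-9`.
#' @return A list of class `residue_comparison`: `fraction_15`, `fraction_60`,
#'   `label`.
#' @export
residue_quench_comparison <- function(series15, series60, tol = 1e-9) {
  conc15 <- vapply(series15, `[[`, numeric(1), "quencher_conc_M")
  conc60 <- vapply(series60, `[[`, numeric(1), "quencher_conc_M")
  if (length(conc15) != length(conc60) || any(conc15 != conc60)) {
    precondition_error("the two series must span the same concentration ladder")
  }
  frac <- function(series) {
    f0 <- locate_peak(series[[1]])$peak_intensity_au
    fl <- locate_peak(series[[length(series)]])$peak_intensity_au
    if (f0 <= 0) validation_error("zero-intensity reference spectrum")
    1 - fl / f0
  }
  f15 <- frac(series15)
  f60 <- frac(series60)
  scale <- max(abs(f15), abs(f60), .Machine$double.eps)
  label <- if (abs(f60 - f15) <= tol * scale) {
    "indeterminate"
  } else if (f60 > f15) {
    "tryptophan-proximal"
  } else {
    "tyrosine-proximal"
  }
  structure(
    list(fraction_15 = f15, fraction_60 = f60, label = label),
    class = "residue_comparison"
  )
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf("<peak_call> %g nm, %.4g a.u.%s\n", x$peak_nm, x$peak_intensity_au,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf("<shift_result> %g -> %g nm (shift %+g nm, %s)%s\n",
              x$start_nm, x$end_nm, x$shift_nm, x$direction,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' @export
print.residue_comparison <- function(x, ...) {
  cat(sprintf("<residue_comparison> dl15 fraction %.4g, dl60 fraction %.4g: %s\n",
              x$fraction_15, x$fraction_60, x$label))
  invisible(x)
}

#' Find peaks in an excitation-emission matrix
#'
#' Local maxima over the 8-neighborhood of the intensity matrix, after
#' masking the first-order Rayleigh ridge (`|em - ex| < scatter_halfwidth_nm`)
#' and its second order (`|em - 2 ex| < scatter_halfwidth_nm`). Peaks weaker
#' than `min_prominence` times the global (unmasked) maximum are dropped;
#' results are sorted by descending intensity.
#'
#' @param x An [eem()].
#' @param min_prominence Fraction of the global unmasked maximum a local
#'   maximum must reach; default 0.1.
#' @param scatter_halfwidth_nm Scatter-ridge mask half-width (nm); default 15.
#' @return A data.frame with columns `excitation_nm`, `emission_nm`,
#'   `intensity_au`, `label`.
#' @export
find_eem_peaks <- function(x, min_prominence = 0.1, scatter_halfwidth_nm = 15) {
  stopifnot(inherits(x, "eem"))
  ex <- x$excitation_grid_nm
  em <- x$emission_grid_nm
  m <- x$intensity_matrix
  exg <- matrix(ex, nrow = length(ex), ncol = length(em))
  emg <- matrix(em, nrow = length(ex), ncol = length(em), byrow = TRUE)
  masked <- abs(emg - exg) < scatter_halfwidth_nm |
    abs(emg - 2 * exg) < scatter_halfwidth_nm
  if (all(masked)) validation_error("scatter mask covers the entire EEM grid")
  work <- m
  work[masked] <- -Inf
  gmax <- max(work)
  if (!is.finite(gmax) || gmax <= 0) {
    return(data.frame(excitation_nm = numeric(0), emission_nm = numeric(0),
                      intensity_au = numeric(0), label = character(0)))
  }
  nr <- nrow(work)
  nc <- ncol(work)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- work
  is_max <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
    is_max <- is_max & (work >= nb)
  }
  hit <- which(is_max & !masked & work >= min_prominence * gmax & work > 0,
               arr.ind = TRUE)
  out <- data.frame(
    excitation_nm = ex[hit[, 1]],
    emission_nm = em[hit[, 2]],
    intensity_au = m[hit],
    label = sprintf("peak (ex %g, em %g)", ex[hit[, 1]], em[hit[, 2]])
  )
  out[order(-out$intensity_au), , drop = FALSE]
}
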