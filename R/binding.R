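# Quenching-table construction, Stern-Volmer and double-logarithmic fits,
# quenching-mechanism classification.

#' Construct a quenching table from peak intensities
#'
#' Builds the Stern-Volmer / double-log coordinate table directly from
#' per-concentration fluorescence intensities (e.g. peak readings reported by
#' an instrument). The first entry must be the quencher-free reference F0.
#' Rows with `[Q] = 0` or with `F >= F0` (not quenched) carry `NA` in the
#' log columns; the latter are counted in the `n_excluded` attribute.
#'
#' @param quencher_conc_M Concentrations (mol/L), starting at 0, strictly
#'   increasing.
#' @param f_au Fluorescence intensities at those concentrations (> 0).
#' @param temperature_K Temperature of the titration (K).
#' @return A data.frame of class `quench_table` (see [build_quench_table()]).
#' @export
quench_table <- function(quencher_conc_M, f_au, temperature_K = 298) {
  if (length(quencher_conc_M) != length(f_au)) {
    validation_error("quencher_conc_M and f_au must have equal length")
  }
  if (quencher_conc_M[1] != 0 || !is_strictly_increasing(quencher_conc_M)) {
    validation_error("concentrations must start at 0 and strictly increase")
  }
  if (any(!is.finite(f_au)) || any(f_au == 0)) {
    qb_stop("F = 0 at some concentration: F0/F undefined", "quenchbind_guard_error")
  }
  f0 <- f_au[1]
  if (f0 <= 0) validation_error("F0 must be > 0")
  quenched <- quencher_conc_M > 0 & f_au < f0
  n_excluded <- sum(quencher_conc_M > 0 & f_au >= f0)
  if (n_excluded > 0) {
    warning(sprintf("%d row(s) with F >= F0 excluded from the double-log columns",
                    n_excluded))
  }
  lg_q <- rep(NA_real_, length(f_au))
  lg_ratio <- rep(NA_real_, length(f_au))
  lg_q[quenched] <- log10(quencher_conc_M[quenched])
  lg_ratio[quenched] <- log10((f0 - f_au[quenched]) / f_au[quenched])
  out <- data.frame(
    quencher_conc_M = quencher_conc_M,
    f_au = f_au,
    f0_over_f = f0 / f_au,
    lg_q = lg_q,
    lg_ratio = lg_ratio
  )
  attr(out, "temperature_K") <- temperature_K
  attr(out, "f0_au") <- f0
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("quench_table", "data.frame")
  out
}

#' Build a quenching table from a titration series
#'
#' For each quencher concentration the fluorescence F is read off the
#' spectrum and tabulated as `F0/F` together with the double-log coordinates
#' `lg[Q]` and `lg((F0 - F)/F)`. Under the default `"fixed"` policy F is read
#' at the wavelength of the zero-quencher (F0) peak, so that a peak drift
#' during the titration is not conflated with quenching; `"per-spectrum"`
#' reads each spectrum's own peak instead.
#'
#' Rows with `[Q] = 0` (the reference itself) and rows where F has not
#' decreased below F0 carry `NA` in the log columns; the number of
#' not-quenched rows is recorded in the `n_excluded` attribute.
#'
#' @param series A [titration_series()].
#' @param peak_policy `"fixed"` (default) or `"per-spectrum"`.
#' @param window_nm Optional peak search window passed to [locate_peak()].
#' @return A data.frame of class `quench_table` with columns
#'   `quencher_conc_M`, `f_au`, `f0_over_f`, `lg_q`, `lg_ratio`; attributes
#'   `temperature_K`, `f0_au`, `f0_peak_nm`, `n_excluded`.
#' @export
build_quench_table <- function(series, peak_policy = c("fixed", "per-spectrum"),
                               window_nm = NULL) {
  stopifnot(inherits(series, "titration_series"))
  peak_policy <- match.arg(peak_policy)
  ref <- series$spectra[[1]]
  p0 <- locate_peak(ref, window_nm = window_nm)
  f0 <- p0$peak_intensity_au
  if (f0 <= 0) validation_error("F0 reference spectrum has zero peak intensity")
  f <- vapply(series$spectra, function(s) {
    if (peak_policy == "fixed") {
      s$intensities_au[which(s$wavelengths_nm == p0$peak_nm)[1]]
    } else {
      locate_peak(s, window_nm = window_nm)$peak_intensity_au
    }
  }, numeric(1))
  out <- quench_table(series$quencher_conc_M, f,
                      temperature_K = series$temperature_K)
  attr(out, "f0_peak_nm") <- p0$peak_nm
  out
}

# r-squared that stays in [0, 1] even for constant responses.
r_squared <- function(y, fitted) {
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    if (ss_res <= .Machine$double.eps * length(y)) 1 else 0
  } else {
    max(0, min(1, 1 - ss_res / ss_tot))
  }
}

#' Fit the Stern-Volmer model
#'
#' Ordinary least squares of `F0/F` on `[Q]` per the Stern-Volmer relation
#' `F0/F = 1 + K_SV [Q] = 1 + K_q tau0 [Q]`. The slope is the Stern-Volmer
#' constant K_SV (L/mol); dividing by the fluorophore lifetime `tau0` gives
#' the bimolecular quenching rate constant K_q, which is compared with the
#' diffusion-limited collisional maximum to classify the quenching mechanism
#' (see [classify_mechanism()]).
#'
#' @param table A [build_quench_table()] result (needs >= 3 rows including
#'   the `[Q] = 0` reference).
#' @param tau0_s Fluorophore lifetime in seconds; default `1e-8`.
#' @param intercept_mode `"free"` (default; intercept reported as a
#'   diagnostic) or `"fixed-at-1"` (regression through the theoretical
#'   intercept).
#' @return A list of class `stern_volmer_fit`: `k_sv`, `k_q`, `intercept`,
#'   `r2`, `tau0_s`, `mechanism`, `negative_slope` flag.
#' @export
fit_stern_volmer <- function(table, tau0_s = 1e-8,
                             intercept_mode = c("free", "fixed-at-1")) {
  intercept_mode <- match.arg(intercept_mode)
  q <- table$quencher_conc_M
  y <- table$f0_over_f
  ok <- is.finite(q) & is.finite(y)
  q <- q[ok]
  y <- y[ok]
  if (length(q) < 3L || !any(q == 0)) {
    precondition_error("need >= 3 rows including the [Q] = 0 reference")
  }
  if (intercept_mode == "free") {
    fit <- stats::lm.fit(cbind(1, q), y)
    intercept <- unname(fit$coefficients[1])
    slope <- unname(fit$coefficients[2])
  } else {
    slope <- sum(q * (y - 1)) / sum(q^2)
    intercept <- 1
  }
  r2 <- r_squared(y, intercept + slope * q)
  k_q <- slope / tau0_s
  negative <- slope < 0
  if (negative) {
    warning("negative Stern-Volmer slope: quenching mechanism undetermined")
  }
  structure(
    list(
      k_sv = slope,
      k_q = k_q,
      intercept = intercept,
      r2 = r2,
      tau0_s = tau0_s,
      mechanism = if (negative) "undetermined" else classify_mechanism(k_q),
      negative_slope = negative
    ),
    class = "stern_volmer_fit"
  )
}

#' Classify the quenching mechanism from K_q
#'
#' Static quenching (ground-state complex formation) is indicated when the
#' bimolecular quenching rate constant exceeds the maximum diffusion-limited
#' collisional rate; otherwise the data are consistent with dynamic
#' (collisional) quenching. The boundary value itself is classified dynamic
#' (strict inequality).
#'
#' @param k_q Quenching rate constant, L/(mol s).
#' @param limit Collisional maximum; default `2.0e10` L/(mol s).
#' @return `"static-consistent"` or `"dynamic-consistent"`.
#' @export
classify_mechanism <- function(k_q, limit = 2.0e10) {
  if (!is.finite(k_q)) validation_error("k_q must be finite")
  if (k_q > limit) "static-consistent" else "dynamic-consistent"
}

#' Fit the double-logarithmic binding model
#'
#' Ordinary least squares of `lg((F0 - F)/F)` on `lg[Q]` per the Hill-type
#' relation `lg((F0-F)/F) = lg K_A + n lg[Q]`: the intercept is `lg K_A`
#' (log10 of the binding constant, L/mol) and the slope is the binding-site
#' number n. Because both coordinates are intensity ratios the fit is
#' invariant to uniform intensity rescaling.
#'
#' @param table A [build_quench_table()] result with >= 3 usable (finite)
#'   double-log rows.
#' @return A list of class `double_log_fit`: `k_a`, `p_ka`, `n`, `r2`,
#'   `n_points`.
#' @export
fit_double_log <- function(table) {
  ok <- is.finite(table$lg_q) & is.finite(table$lg_ratio)
  x <- table$lg_q[ok]
  y <- table$lg_ratio[ok]
  if (length(x) < 3L) {
    precondition_error("need >= 3 rows with finite double-log coordinates")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  p_ka <- unname(fit$coefficients[1])
  n <- unname(fit$coefficients[2])
  structure(
    list(
      k_a = 10^p_ka,
      p_ka = p_ka,
      n = n,
      r2 = r_squared(y, p_ka + n * x),
      n_points = length(x)
    ),
    class = "double_log_fit"
  )
}

#' @export
print.stern_volmer_fit <- function(x, ...) {
  cat(sprintf(
    "<stern_volmer_fit> K_SV = %.6g L/mol, K_q = %.6g L/(mol s), intercept = %.4f, r2 = %.4f, %s\n",
    x$k_sv, x$k_q, x$intercept, x$r2, x$mechanism
  ))
  invisible(x)
}

#' @export
print.double_log_fit <- function(x, ...) {
  cat(sprintf(
    "<double_log_fit> pK_A = %.4f (K_A = %.4g L/mol), n = %.4f, r2 = %.4f (%d points)\n",
    x$p_ka, x$k_a, x$n, x$r2, x$n_points
  ))
  invisible(x)
}
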