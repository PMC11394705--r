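# Van't Hoff thermodynamics: enthalpy/entropy from the temperature dependence
# of the binding constant, Gibbs free energy, driving-force classification.

#' Van't Hoff fit of enthalpy and entropy changes
#'
#' Least squares of `ln K_A` on `1/T` per the Van't Hoff relation
#' `ln K_A = -dH/(R T) + dS/R` with R = 8.314 J/(mol K): the slope is
#' `-dH/R` and the intercept `dS/R`. With exactly two temperatures this is
#' the exact two-point solution.
#'
#' @param ka_by_T Named numeric vector: names are temperatures (K), values the
#'   binding constants K_A (L/mol, > 0). Alternatively pass `temperatures_K`.
#' @param temperatures_K Optional explicit temperature vector (K) matching
#'   `ka_by_T`.
#' @return A list of class `vant_hoff_fit`: `delta_h_J_mol`, `delta_s_J_molK`,
#'   `r2`, `temperatures_K`, `ka`.
#' @export
fit_vant_hoff <- function(ka_by_T, temperatures_K = NULL) {
  ka <- as.numeric(ka_by_T)
  temps <- if (is.null(temperatures_K)) as.numeric(names(ka_by_T)) else as.numeric(temperatures_K)
  if (length(temps) != length(ka) || anyNA(temps)) {
    precondition_error("temperatures (K) must be supplied as names or via temperatures_K")
  }
  if (any(!is.finite(ka)) || any(ka <= 0)) {
    validation_error("all binding constants must be finite and > 0")
  }
  if (any(temps <= 0)) validation_error("temperatures must be > 0 K")
  dup <- duplicated(temps)
  if (any(dup)) {
    for (t in unique(temps[dup])) {
      if (length(unique(ka[temps == t])) > 1L) {
        validation_error(sprintf("conflicting K_A values at duplicate temperature %g K", t))
      }
    }
    keep <- !dup
    temps <- temps[keep]
    ka <- ka[keep]
  }
  if (length(unique(temps)) < 2L) {
    precondition_error("need >= 2 distinct temperatures")
  }
  x <- 1 / temps
  y <- log(ka)
  fit <- stats::lm.fit(cbind(1, x), y)
  intercept <- unname(fit$coefficients[1])
  slope <- unname(fit$coefficients[2])
  structure(
    list(
      delta_h_J_mol = -R_GAS * slope,
      delta_s_J_molK = R_GAS * intercept,
      r2 = r_squared(y, intercept + slope * x),
      temperatures_K = temps,
      ka = ka
    ),
    class = "vant_hoff_fit"
  )
}

#' Gibbs free energy change
#'
#' Evaluates the Gibbs-Helmholtz relation `dG = dH - T dS`.
#'
#' @param delta_h_J_mol Enthalpy change (J/mol).
#' @param delta_s_J_molK Entropy change (J/(mol K)).
#' @param temperature_K Temperature(s) in K, > 0 (vectorized).
#' @return Free energy change(s) in J/mol.
#' @export
gibbs_free_energy <- function(delta_h_J_mol, delta_s_J_molK, temperature_K) {
  if (!all(is.finite(c(delta_h_J_mol, delta_s_J_molK, temperature_K)))) {
    validation_error("all inputs must be finite")
  }
  if (any(temperature_K <= 0)) precondition_error("temperature must be > 0 K")
  delta_h_J_mol - temperature_K * delta_s_J_molK
}

#' Classify the dominant binding force from thermodynamic signs
#'
#' Sign-based classification: `dH < 0, dS < 0` indicates hydrogen bonding and
#' van der Waals contacts; `dH > 0, dS > 0` hydrophobic interaction;
#' `dH < 0, dS > 0` electrostatic interaction. Values within `zero_tol` of 0,
#' and the `dH > 0, dS < 0` quadrant (not covered by the rules), are labelled
#' indeterminate.
#'
#' @param delta_h_J_mol Enthalpy change (J/mol).
#' @param delta_s_J_molK Entropy change (J/(mol K)).
#' @param zero_tol Length-2 numeric `c(h, s)`: absolute tolerances (J/mol and
#'   J/(mol K)) inside which a value counts as zero; default `c(1e-9, 1e-9)`.
#' @return One of `"hydrogen-bond+van-der-Waals"`, `"hydrophobic"`,
#'   `"electrostatic"`, `"indeterminate"`.
#' @export
classify_forces <- function(delta_h_J_mol, delta_s_J_molK,
                            zero_tol = c(1e-9, 1e-9)) {
  if (!all(is.finite(c(delta_h_J_mol, delta_s_J_molK)))) {
    validation_error("delta_h and delta_s must be finite")
  }
  h_zero <- abs(delta_h_J_mol) <= zero_tol[1]
  s_zero <- abs(delta_s_J_molK) <= zero_tol[2]
  if (h_zero || s_zero) return("indeterminate")
  if (delta_h_J_mol < 0 && delta_s_J_molK < 0) return("hydrogen-bond+van-der-Waals")
  if (delta_h_J_mol > 0 && delta_s_J_molK > 0) return("hydrophobic")
  if (delta_h_J_mol < 0 && delta_s_J_molK > 0) return("electrostatic")
  "indeterminate"
}

#' Full thermodynamic analysis from binding constants
#'
#' Convenience wrapper: Van't Hoff fit, per-temperature Gibbs free energy and
#' driving-force classification in one call.
#'
#' @inheritParams fit_vant_hoff
#' @param zero_tol Passed to [classify_forces()].
#' @return A list of class `thermo_result`: `delta_h_J_mol`, `delta_s_J_molK`,
#'   `delta_g_by_T` (named, J/mol), `gas_constant_J_molK`, `force_label`, `r2`.
#' @export
thermo_analysis <- function(ka_by_T, temperatures_K = NULL,
                            zero_tol = c(1e-9, 1e-9)) {
  fit <- fit_vant_hoff(ka_by_T, temperatures_K)
  dg <- gibbs_free_energy(fit$delta_h_J_mol, fit$delta_s_J_molK, fit$temperatures_K)
  names(dg) <- as.character(fit$temperatures_K)
  structure(
    list(
      delta_h_J_mol = fit$delta_h_J_mol,
      delta_s_J_molK = fit$delta_s_J_molK,
      delta_g_by_T = dg,
      gas_constant_J_molK = R_GAS,
      force_label = classify_forces(fit$delta_h_J_mol, fit$delta_s_J_molK, zero_tol),
      r2 = fit$r2
    ),
    class = "thermo_result"
  )
}

#' Celsius to Kelvin
#'
#' Integer-Kelvin convention by default (`+273`, so 30 C -> 303 K), matching
#' common reporting practice in binding studies; `offset = 273.15` gives the
#' exact conversion.
#'
#' @param celsius Temperature(s) in degrees Celsius.
#' @param offset Additive offset; default 273.
#' @return Temperature(s) in K.
#' @export
celsius_to_kelvin <- function(celsius, offset = 273) {
  celsius + offset
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> dH = %.2f kJ/mol, dS = %.2f J/(mol K), force: %s\n",
              x$delta_h_J_mol / 1000, x$delta_s_J_molK, x$force_label))
  for (t in names(x$delta_g_by_T)) {
    cat(sprintf("  dG(%s K) = %.2f kJ/mol\n", t, x$delta_g_by_T[[t]] / 1000))
  }
  invisible(x)
}
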