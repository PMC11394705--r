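# Enzyme-inhibition assay: inhibition percentages and IC50 estimation.

#' Inhibition percentage from control and sample absorbances
#'
#' `S = (a0 - a1)/a0 * 100`. Negative values (apparent activation) are passed
#' through; the returned vector carries an `n_activation` attribute counting
#' them.
#'
#' @param a0 Control absorbance(s), > 0.
#' @param a1 Sample absorbance(s), >= 0 (recycled against `a0`).
#' @return Inhibition percentage(s).
#' @export
inhibition_rate <- function(a0, a1) {
  if (any(!is.finite(a0)) || any(a0 <= 0)) {
    qb_stop("a0 must be finite and > 0", "quenchbind_guard_error")
  }
  if (any(!is.finite(a1)) || any(a1 < 0)) {
    validation_error("a1 must be finite and >= 0")
  }
  s <- (a0 - a1) / a0 * 100
  attr(s, "n_activation") <- sum(s < 0)
  s
}

# Four-parameter logistic in concentration space:
# S(c) = bottom + (top - bottom) / (1 + (ic50/c)^h)
four_pl <- function(conc, bottom, top, ic50, h) {
  bottom + (top - bottom) / (1 + (ic50 / conc)^h)
}

# Log-linear interpolation of the 50% crossing.
interp_ic50 <- function(conc, inh) {
  above <- inh >= 50
  if (all(above) || !any(above)) {
    precondition_error("inhibition does not cross 50%: interpolation impossible")
  }
  i <- which(!above & c(above[-1], FALSE))[1]  # last below-50 before a crossing
  if (is.na(i)) {
    i <- which(diff(above) == 1)[1]
  }
  lc <- log10(conc)
  10^(lc[i] + (50 - inh[i]) * (lc[i + 1] - lc[i]) / (inh[i + 1] - inh[i]))
}

fit_4pl_core <- function(conc, inh) {
  sse <- function(par) {
    pred <- four_pl(conc, par[1], par[2], 10^par[3], exp(par[4]))
    sum((inh - pred)^2)
  }
  lo <- c(-10, 50, log10(min(conc)) - 3, log(1e-3))
  hi <- c(50, 110, log10(max(conc)) + 3, log(1e3))
  ic50_0 <- tryCatch(interp_ic50(conc, inh),
                     error = function(e) sqrt(min(conc) * max(conc)))
  start <- c(
    max(-9.9, min(min(inh), 49.9)),
    min(109.9, max(max(inh), 50.1)),
    log10(ic50_0),
    log(1)
  )
  start <- pmin(pmax(start, lo + 1e-9), hi - 1e-9)
  best <- NULL
  for (h0 in c(0, log(0.5), log(2))) {
    st <- start
    st[4] <- min(max(h0, lo[4] + 1e-9), hi[4] - 1e-9)
    res <- tryCatch(
      stats::optim(st, sse, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 1000, factr = 10)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    qb_stop("4PL fit failed to converge", "quenchbind_convergence_error")
  }
  par <- best$par
  rss <- best$value
  # Gauss-Newton polish: the quasi-Newton solution is accurate to ~1e-5
  # relative; a bounded nls step from there reaches machine precision.
  polish <- tryCatch(
    suppressWarnings(stats::nls(
      inh ~ bottom + (top - bottom) / (1 + (ic50 / conc)^h),
      data = data.frame(conc = conc, inh = inh),
      start = list(bottom = par[1], top = par[2], ic50 = 10^par[3],
                   h = exp(par[4])),
      algorithm = "port",
      lower = c(bottom = -10, top = 50, ic50 = 10^lo[3], h = exp(lo[4])),
      upper = c(bottom = 50, top = 110, ic50 = 10^hi[3], h = exp(hi[4])),
      control = stats::nls.control(maxiter = 500, tol = 1e-12, warnOnly = TRUE)
    )),
    error = function(e) NULL
  )
  if (!is.null(polish)) {
    cf <- stats::coef(polish)
    rss_polish <- sum(stats::resid(polish)^2)
    if (rss_polish <= rss) {
      return(list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
                  ic50 = unname(cf["ic50"]), h = unname(cf["h"]),
                  rss = rss_polish))
    }
  }
  list(
    bottom = par[1],
    top = par[2],
    ic50 = 10^par[3],
    h = exp(par[4]),
    rss = rss
  )
}

#' Fit an IC50 from a dose-response table
#'
#' Converts absorbances to inhibition percentages via [inhibition_rate()],
#' averages replicate wells per concentration (carrying the per-concentration
#' SD into the diagnostics), and estimates the half-inhibitory concentration.
#' The default model is the four-parameter logistic
#' `S = bottom + (top - bottom) / (1 + (IC50/c)^h)` fitted by bounded least
#' squares (`bottom` in `[-10, 50]`, `top` in `[50, 110]`, `h > 0`); the
#' `"interpolation"` model is a model-free log-linear interpolation of the 50%
#' crossing, useful as a sanity cross-check.
#'
#' @param table A [dose_response_table()] (or a data.frame with columns
#'   `conc_ug_ml`, `a0`, `a1`; duplicate concentrations are treated as
#'   replicates and averaged).
#' @param model `"4PL"` (default) or `"interpolation"`.
#' @param n_boot Bootstrap replicates for a percentile confidence interval on
#'   the IC50 by case resampling; 0 (default) disables it.
#' @param seed RNG seed for the bootstrap.
#' @return A list of class `inhibition_curve`: `rows` (conc, inhibition_pct,
#'   sd_pct, n_rep), `model`, `ic50`, `ic50_ci`, `params` (4PL parameters or
#'   NULL), `diagnostics`.
#' @export
fit_ic50 <- function(table, model = c("4PL", "interpolation"),
                     n_boot = 0, seed = NULL) {
  model <- match.arg(model)
  df <- as.data.frame(table)
  if (!all(c("conc_ug_ml", "a0", "a1") %in% names(df))) {
    precondition_error("table must have columns conc_ug_ml, a0, a1")
  }
  inh_all <- inhibition_rate(df$a0, df$a1)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(df)), df$conc_ug_ml), function(i) {
    data.frame(
      conc_ug_ml = df$conc_ug_ml[i][1],
      inhibition_pct = mean(inh_all[i]),
      sd_pct = if (length(i) > 1) stats::sd(inh_all[i]) else NA_real_,
      n_rep = length(i)
    )
  }))
  agg <- agg[order(agg$conc_ug_ml), , drop = FALSE]
  rownames(agg) <- NULL
  conc <- agg$conc_ug_ml
  inh <- agg$inhibition_pct

  if (model == "4PL") {
    if (length(conc) < 4L) precondition_error("4PL needs >= 4 distinct concentrations")
    fit <- fit_4pl_core(conc, inh)
    ic50 <- fit$ic50
    params <- fit[c("bottom", "top", "h")]
    resid <- inh - four_pl(conc, fit$bottom, fit$top, fit$ic50, fit$h)
    diagnostics <- list(rss = fit$rss, residual_sd = stats::sd(resid),
                        max_abs_residual = max(abs(resid)))
  } else {
    ic50 <- interp_ic50(conc, inh)
    params <- NULL
    diagnostics <- list(rss = NA_real_, residual_sd = NA_real_,
                        max_abs_residual = NA_real_)
  }

  ic50_ci <- NULL
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(df), replace = TRUE)
        tryCatch({
          sub <- df[idx, , drop = FALSE]
          fit_ic50(sub, model = model, n_boot = 0)$ic50
        }, error = function(e) NA_real_)
      }, numeric(1))
    })
    ic50_ci <- unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }

  structure(
    list(
      rows = agg,
      model = if (model == "4PL") "four-parameter-logistic" else "log-linear-interpolation",
      ic50 = ic50,
      ic50_ci = ic50_ci,
      params = params,
      diagnostics = diagnostics
    ),
    class = "inhibition_curve"
  )
}

#' @export
print.inhibition_curve <- function(x, ...) {
  ci <- if (is.null(x$ic50_ci)) "" else sprintf(" (95%% CI %.4g-%.4g)", x$ic50_ci[1], x$ic50_ci[2])
  cat(sprintf("<inhibition_curve> %s: IC50 = %.4g ug/mL%s, %d concentrations\n",
              x$model, x$ic50, ci, nrow(x$rows)))
  invisible(x)
}
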