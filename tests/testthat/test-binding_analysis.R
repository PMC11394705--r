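# Quench table, Stern-Volmer fit, mechanism classification, double-log fit.

test_that("build_quench_table computes F0/F and the double-log coordinates", {
  ser <- sv_series(k_sv = 43541)
  qt <- build_quench_table(ser)
  expect_identical(qt$f0_over_f[1], 1)              # F0 row by definition
  expect_true(all(is.na(qt$lg_q[1])))               # [Q]=0 excluded from lg
  expect_equal(qt$f0_over_f, 1 + 43541 * qt$quencher_conc_M, tolerance = 1e-12)
  expect_identical(attr(qt, "f0_peak_nm"), 338)
  expect_identical(attr(qt, "n_excluded"), 0L)

  # printed-intensity ratio: 642.644 / 239.602
  expect_equal(642.644 / 239.602, 2.6821, tolerance = 2e-5)

  # a row with F >= F0 is kept in f0_over_f but dropped from the lg columns
  s0 <- gaussian_spectrum(height = 600, conc = 0)
  s1 <- gaussian_spectrum(height = 610, conc = 1e-5)  # above F0
  s2 <- gaussian_spectrum(height = 300, conc = 2e-5)
  ser2 <- titration_series(list(s0, s1, s2))
  expect_warning(qt2 <- build_quench_table(ser2), "excluded")
  expect_identical(attr(qt2, "n_excluded"), 1L)
  expect_false(is.na(qt2$f0_over_f[2]))
  expect_true(is.na(qt2$lg_ratio[2]))
  expect_false(is.na(qt2$lg_ratio[3]))

  # F = 0 somewhere -> guard error
  wl <- 300:450
  sz <- emission_spectrum(wl, c(rep(1, 38), 0, rep(1, length(wl) - 39)) * 0,
                          280, 303, 1e-5)
  expect_error(build_quench_table(titration_series(list(s0, sz))),
               class = "quenchbind_guard_error")
})

test_that("per-spectrum peak policy differs from fixed policy under drift", {
  ser <- simulate_titration_series(peak_drift_nm = -6, n = 1)
  qt_fixed <- build_quench_table(ser, peak_policy = "fixed")
  qt_peak <- build_quench_table(ser, peak_policy = "per-spectrum")
  # the drifted band's own peak is higher than its value at the F0 wavelength
  last <- nrow(qt_fixed)
  expect_gt(qt_peak$f_au[last], qt_fixed$f_au[last])
})

test_that("fit_stern_volmer recovers an exact line and classifies mechanism", {
  qt <- build_quench_table(sv_series(k_sv = 43541))
  fit <- fit_stern_volmer(qt)  # tau0 default 1e-8 s
  expect_equal(fit$k_sv, 43541, tolerance = 1e-10)
  expect_equal(fit$k_q, 4.3541e12, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_identical(fit$mechanism, "static-consistent")
  expect_equal(fit$k_q / fit$k_sv, 1 / fit$tau0_s, tolerance = 1e-12)

  # fixed-at-1 intercept gives the same slope on exact data
  fit1 <- fit_stern_volmer(qt, intercept_mode = "fixed-at-1")
  expect_equal(fit1$k_sv, fit$k_sv, tolerance = 1e-10)
  expect_identical(fit1$intercept, 1)

  # constant F0/F = 1 -> zero slope (all rows unquenched, hence the warning)
  qt0 <- suppressWarnings(build_quench_table(sv_series(k_sv = 0)))
  fit0 <- fit_stern_volmer(qt0)
  expect_equal(fit0$k_sv, 0, tolerance = 1e-9)
  expect_identical(fit0$mechanism, "dynamic-consistent")

  # too few points -> error
  expect_error(fit_stern_volmer(qt[1:2, ]),
               class = "quenchbind_precondition_error")

  # negative slope -> warning + undetermined mechanism
  qt_neg <- qt
  qt_neg$f0_over_f <- rev(qt$f0_over_f)
  expect_warning(fneg <- fit_stern_volmer(qt_neg), "negative")
  expect_identical(fneg$mechanism, "undetermined")
  expect_true(fneg$negative_slope)
})

test_that("classify_mechanism uses a strict threshold", {
  expect_identical(classify_mechanism(4.3541e12), "static-consistent")
  expect_identical(classify_mechanism(1e9), "dynamic-consistent")
  expect_identical(classify_mechanism(2.0e10), "dynamic-consistent")  # boundary
  expect_error(classify_mechanism(NaN), class = "quenchbind_validation_error")
})

test_that("fit_double_log recovers generative truths exactly", {
  for (truth in list(c(p_ka = 6.7420, n = 1.4409),
                     c(p_ka = 4.2702, n = 0.9079),
                     c(p_ka = 0, n = 1))) {
    ser <- simulate_titration_series(p_ka = truth["p_ka"], n = truth["n"])
    fit <- fit_double_log(build_quench_table(ser))
    expect_equal(fit$p_ka, unname(truth["p_ka"]), tolerance = 1e-10)
    expect_equal(fit$n, unname(truth["n"]), tolerance = 1e-10)
    expect_equal(fit$k_a, 10^unname(truth["p_ka"]), tolerance = 1e-9)
    expect_equal(fit$r2, 1, tolerance = 1e-10)
  }
  # < 3 usable rows -> error
  ser <- simulate_titration_series(conc_ladder_M = c(0, 1e-5, 2e-5))
  qt <- build_quench_table(ser)
  expect_error(fit_double_log(qt[qt$quencher_conc_M < 2e-5, ]),
               class = "quenchbind_precondition_error")
})

test_that("fit_double_log is invariant to uniform intensity scaling", {
  ser <- simulate_titration_series(p_ka = 5.5, n = 1.2)
  scaled <- titration_series(lapply(ser$spectra, function(s) {
    s$intensities_au <- s$intensities_au * 7.5
    s
  }))
  f1 <- fit_double_log(build_quench_table(ser))
  f2 <- fit_double_log(build_quench_table(scaled))
  expect_equal(f1$p_ka, f2$p_ka, tolerance = 1e-12)
  expect_equal(f1$n, f2$n, tolerance = 1e-12)
})

test_that("double-log estimator is stable under 1% noise added to F", {
  # median p_ka over 200 seeded replicates within 0.02 of truth
  p_truth <- 6.7420
  n_truth <- 1.4409
  f0 <- 642.644
  conc <- c(0, 3, 6, 12, 25, 50, 100) * 1e-6
  f_true <- c(f0, f0 / (1 + 10^p_truth * conc[-1]^n_truth))
  set.seed(1000)
  est <- vapply(1:200, function(b) {
    f <- pmax(f_true + stats::rnorm(length(f_true), sd = 0.01 * f0), 1e-3)
    qt <- suppressWarnings(quench_table(conc, f))
    fit_double_log(qt)$p_ka
  }, numeric(1))
  expect_lt(abs(stats::median(est) - p_truth), 0.02)
})

test_that("quench_table validates its inputs", {
  expect_error(quench_table(c(1e-6, 2e-6), c(100, 90)),
               class = "quenchbind_validation_error")  # no F0 row
  expect_error(quench_table(c(0, 1e-6), c(100, 0)),
               class = "quenchbind_guard_error")
  qt <- quench_table(c(0, 1e-6, 2e-6), c(100, 80, 60), temperature_K = 310)
  expect_identical(attr(qt, "temperature_K"), 310)
  expect_equal(qt$lg_ratio[2], log10(20 / 80), tolerance = 1e-12)
})
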