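# Inner-filter correction, peak location/shift, synchronous comparison, EEM peaks.

test_that("inner-filter correction evaluates the closed form and its properties", {
  s <- gaussian_spectrum(a_ex = 0.1, a_em = 0.3)
  s$intensities_au <- rep(100, length(s$wavelengths_nm))
  out <- correct_inner_filter(s)
  # 100 * e^((0.1+0.3)/2) = 122.1402758...
  expect_equal(out$intensities_au[1], 100 * exp(0.2), tolerance = 1e-12)
  expect_equal(out$intensities_au[1], 122.1402758, tolerance = 1e-7)
  expect_true(out$corrected)

  # identity at zero absorbance
  s0 <- gaussian_spectrum(a_ex = 0, a_em = 0)
  expect_identical(correct_inner_filter(s0)$intensities_au, s0$intensities_au)

  # a_ex + a_em = 2, base e -> uniform factor e
  s2 <- gaussian_spectrum(a_ex = 1.5, a_em = 0.5)
  expect_equal(correct_inner_filter(s2)$intensities_au / s2$intensities_au,
               rep(exp(1), length(s2$intensities_au)), tolerance = 1e-12)

  # base-10 escape hatch
  expect_equal(correct_inner_filter(s2, base = 10)$intensities_au,
               s2$intensities_au * 10, tolerance = 1e-12)

  # missing absorbances -> precondition error
  s3 <- gaussian_spectrum()
  s3$a_ex <- NULL
  expect_error(correct_inner_filter(s3), class = "quenchbind_precondition_error")
})

test_that("inner-filter correction is multiplicative and invertible", {
  s <- gaussian_spectrum(a_ex = 0.07, a_em = 0.21)
  for (c_scale in c(0.5, 3, 10)) {
    scaled <- s
    scaled$intensities_au <- s$intensities_au * c_scale
    expect_equal(correct_inner_filter(scaled)$intensities_au,
                 correct_inner_filter(s)$intensities_au * c_scale,
                 tolerance = 1e-12)
  }
  out <- correct_inner_filter(s)
  expect_equal(out$intensities_au / exp((s$a_ex + s$a_em) / 2),
               s$intensities_au, tolerance = 1e-15)
})

test_that("locate_peak finds maxima, breaks ties low, handles degeneracy", {
  s <- gaussian_spectrum(center = 338)
  p <- locate_peak(s)
  expect_identical(p$peak_nm, 338)
  expect_false(p$degenerate)

  # two equal maxima -> lowest wavelength
  wl <- 300:450
  au <- rep(0.5, length(wl))
  au[wl == 330] <- 10
  au[wl == 340] <- 10
  tie <- emission_spectrum(wl, au, 280, 303, 0)
  expect_identical(locate_peak(tie)$peak_nm, 330)

  # scaling invariance
  s10 <- s
  s10$intensities_au <- s$intensities_au * 17.3
  expect_identical(locate_peak(s10)$peak_nm, locate_peak(s)$peak_nm)

  # all-zero spectrum: lowest wavelength, degenerate flag
  z <- emission_spectrum(wl, rep(0, length(wl)), 280, 303, 0)
  pz <- locate_peak(z)
  expect_identical(pz$peak_nm, 300)
  expect_identical(pz$peak_intensity_au, 0)
  expect_true(pz$degenerate)

  # window restriction and empty window error
  expect_identical(locate_peak(tie, window_nm = c(335, 345))$peak_nm, 340)
  expect_error(locate_peak(s, window_nm = c(500, 600)),
               class = "quenchbind_precondition_error")
})

test_that("smoothed peak location is robust to 1% noise (Monte-Carlo)", {
  wl <- seq(300, 450, by = 1)
  clean <- 600 * exp(-0.5 * ((wl - 338) / 12)^2)
  hits <- 0L
  set.seed(42)
  for (rep in 1:100) {
    noisy <- pmax(clean + rnorm(length(wl), sd = 6), 0)  # sigma = 1% of height
    s <- emission_spectrum(wl, noisy, 280, 303, 0)
    p <- locate_peak(s, smooth = 7)
    if (abs(p$peak_nm - 338) <= 1) hits <- hits + 1L
  }
  expect_gte(hits, 99L)
})

test_that("peak_shift_series tracks blue/red/none shifts", {
  ser <- simulate_titration_series(peak_drift_nm = -2)
  sh <- peak_shift_series(ser)
  expect_identical(sh$shift_nm, -2)
  expect_identical(sh$direction, "blue")
  expect_identical(sh$start_nm, 338)
  expect_identical(sh$end_nm, 336)

  flat <- simulate_titration_series(peak_drift_nm = 0)
  sh0 <- peak_shift_series(flat)
  expect_identical(sh0$shift_nm, 0)
  expect_identical(sh0$direction, "none")

  red <- simulate_titration_series(peak_drift_nm = 3)
  expect_identical(peak_shift_series(red)$direction, "red")

  # synchronous tyrosine channel drifting 293 -> 291
  pair <- simulate_synchronous_pair()
  sh15 <- peak_shift_series(pair$series15)
  expect_identical(sh15$start_nm, 293)
  expect_identical(sh15$end_nm, 291)
  expect_identical(sh15$shift_nm, -2)
  expect_identical(sh15$direction, "blue")
})

test_that("residue_quench_comparison applies the proximity rule symmetrically", {
  pair <- simulate_synchronous_pair()  # fractions 0.4 / 0.6
  cmp <- residue_quench_comparison(pair$series15, pair$series60)
  expect_equal(cmp$fraction_15, 0.4, tolerance = 1e-12)
  expect_equal(cmp$fraction_60, 0.6, tolerance = 1e-12)
  expect_identical(cmp$label, "tryptophan-proximal")

  # rule symmetry: swap the channels' quench depths
  pair2 <- simulate_synchronous_pair(
    truth15 = list(center_nm = 293, width_nm = 12, f0_au = 400,
                   quench_fraction = 0.6, drift_nm = 0, delta_lambda_nm = 15,
                   excitation_grid_nm = seq(265, 350, by = 1)),
    truth60 = list(center_nm = 285, width_nm = 12, f0_au = 600,
                   quench_fraction = 0.4, drift_nm = 0, delta_lambda_nm = 60,
                   excitation_grid_nm = seq(220, 350, by = 1))
  )
  expect_identical(residue_quench_comparison(pair2$series15, pair2$series60)$label,
                   "tyrosine-proximal")

  # equal fractions -> indeterminate
  pair3 <- simulate_synchronous_pair(
    truth15 = list(center_nm = 293, width_nm = 12, f0_au = 400,
                   quench_fraction = 0, drift_nm = 0, delta_lambda_nm = 15,
                   excitation_grid_nm = seq(265, 350, by = 1)),
    truth60 = list(center_nm = 285, width_nm = 12, f0_au = 600,
                   quench_fraction = 0, drift_nm = 0, delta_lambda_nm = 60,
                   excitation_grid_nm = seq(220, 350, by = 1))
  )
  cmp3 <- residue_quench_comparison(pair3$series15, pair3$series60)
  expect_identical(cmp3$label, "indeterminate")
  expect_identical(cmp3$fraction_15, 0)

  # mismatched ladders -> error
  expect_error(
    residue_quench_comparison(pair$series15[-2], pair$series60),
    class = "quenchbind_precondition_error"
  )
})

test_that("find_eem_peaks detects planted peaks and respects scatter masks", {
  e <- simulate_eem()
  peaks <- find_eem_peaks(e)
  expect_identical(nrow(peaks), 2L)
  expect_identical(peaks$excitation_nm, c(280, 226))
  expect_identical(peaks$emission_nm, c(338, 338))
  expect_true(all(diff(peaks$intensity_au) <= 0))  # sorted descending

  # flat zero matrix -> empty
  ez <- eem(seq(220, 300, 2), seq(300, 450, 2),
            matrix(0, 41, 76))
  expect_identical(nrow(find_eem_peaks(ez)), 0L)

  # a (narrow) peak on the Rayleigh diagonal is masked out; the real one stays
  ed <- simulate_eem(peaks = data.frame(excitation_nm = c(280, 300),
                                        emission_nm = c(400, 304),
                                        height_au = c(1000, 800)),
                     width_ex_nm = 2, width_em_nm = 3)
  pd <- find_eem_peaks(ed)
  expect_identical(nrow(pd), 1L)
  expect_identical(pd$excitation_nm, 280)
  expect_identical(pd$emission_nm, 400)

  # output invariant to changes strictly inside the masked ridges
  e2 <- e
  ex <- e2$excitation_grid_nm
  em <- e2$emission_grid_nm
  exg <- matrix(ex, length(ex), length(em))
  emg <- matrix(em, length(ex), length(em), byrow = TRUE)
  masked <- abs(emg - exg) < 15 | abs(emg - 2 * exg) < 15
  e2$intensity_matrix[masked] <- e2$intensity_matrix[masked] + 5000
  peaks2 <- find_eem_peaks(e2)
  expect_identical(peaks2$excitation_nm, peaks$excitation_nm)
  expect_identical(peaks2$emission_nm, peaks$emission_nm)

  # mask covering the entire grid -> error
  expect_error(find_eem_peaks(e, scatter_halfwidth_nm = 1000),
               class = "quenchbind_validation_error")
})
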