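test_that("baseline subtraction removes linear drift exactly", {
  th <- gen_thermogram(pre_amplitude = 0)
  flat <- baseline_subtract(th)
  expect_equal(flat$cp_excess, th$cp_excess, tolerance = 1e-9)

  drift <- gen_thermogram(pre_amplitude = 0, baseline_slope = 0.4,
                          baseline_intercept = 2)
  fixed <- baseline_subtract(drift)
  expect_equal(fixed$cp_excess, th$cp_excess, tolerance = 1e-9)
  k <- floor(0.05 * length(fixed$cp_excess))
  expect_lt(abs(mean(fixed$cp_excess[1:k])), 1e-6 * max(fixed$cp_excess))
  expect_lt(abs(mean(tail(fixed$cp_excess, k))), 1e-6 * max(fixed$cp_excess))
})

test_that("a peak overlapping a flank is detected", {
  th <- gen_thermogram(t_m_C = 26.5, pre_amplitude = 0, t_range_C = c(25, 50))
  expect_error(baseline_subtract(th, flank_fraction = 0.1), "flank")
})

test_that("transition detection finds the expected peaks", {
  none <- thermogram(seq(25, 50, by = 0.01), rep(1, 2501))
  expect_equal(nrow(detect_transitions(none)), 0L)

  ctl <- baseline_subtract(gen_thermogram())  # main + pretransition
  pk <- detect_transitions(ctl)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$t_peak_C, c(34.0, 41.2), tolerance = 0.01 / 34)

  solo <- baseline_subtract(gen_thermogram(pre_amplitude = 0))
  expect_equal(nrow(detect_transitions(solo)), 1L)
})

test_that("main-transition features match the generator and geometry", {
  th <- baseline_subtract(gen_thermogram(pre_amplitude = 0))
  f <- main_transition_features(th)
  expect_equal(f$t_m_C, 41.2, tolerance = 0.01 / 41.2)
  expect_equal(f$t_half_C, 0.5, tolerance = 0.02 / 0.5)

  # symmetric triangular peak of half-base w has FWHM w
  tC <- seq(30, 50, by = 0.01)
  w <- 2
  y <- pmax(0, 1 - abs(tC - 40) / w)
  tri <- thermogram(tC, y)
  ft <- main_transition_features(tri)
  expect_equal(ft$t_half_C, w, tolerance = 0.02 / w)
  expect_equal(ft$t_m_C, 40, tolerance = 0.01)
})

test_that("measured width matches the van't Hoff closed form across the sweep", {
  for (tm in c(30, 45, 60)) {
    for (dh in c(5e5, 2e6, 1e7)) {
      fw <- vant_hoff_fwhm(dh, tm)
      th <- gen_thermogram(t_m_C = tm, dh_vh_J_mol = dh, pre_amplitude = 0,
                           t_range_C = tm + c(-20, 20), grid_step_C = 0.01)
      f <- main_transition_features(baseline_subtract(th))
      expect_lt(abs(f$t_half_C - fw), 0.011)
      # the Cp apex sits ~4 R^2 Tm^3 / dH^2 below Tm (1/T^2 prefactor);
      # noticeable only for the broadest transitions in the sweep
      expect_lt(abs(f$t_m_C - tm), 0.05)
    }
  }
})

test_that("half-height must be bracketed on both sides", {
  tC <- seq(41.0, 43, by = 0.01)  # scan starts above the lower half-height
  tmK <- 41.2 + 273.15
  dh <- vant_hoff_enthalpy_for_fwhm(41.2, 0.5)
  K <- exp((dh / 8.314) * (1 / tmK - 1 / (tC + 273.15)))
  y <- K / (1 + K)^2
  th <- thermogram(tC, y)
  pk <- detect_transitions(th)
  expect_error(main_transition_features(th, pk[which.max(pk$height), ]),
               "not bracketed")
})

test_that("pretransition detection applies the prominence rule", {
  flat <- baseline_subtract(gen_thermogram())
  main <- main_transition_features(flat)
  pre <- pretransition_features(flat, main)
  expect_false(pre$suppressed)
  expect_equal(pre$t_pre_C, 34.0, tolerance = 0.02 / 34)

  gone <- baseline_subtract(gen_thermogram(pre_amplitude = 0))
  main2 <- main_transition_features(gone)
  expect_true(pretransition_features(gone, main2)$suppressed)

  faint <- baseline_subtract(gen_thermogram(pre_amplitude = 0.02))
  main3 <- main_transition_features(faint)
  expect_true(pretransition_features(faint, main3)$suppressed)

  expect_error(pretransition_features(flat, main,
                                      search_window = c(34, 41.1)),
               "main peak")
})

test_that("feature extraction is invariant to heat-capacity scaling", {
  th <- gen_thermogram()
  f1 <- extract_transition_features(th)
  th$cp_excess <- th$cp_excess * 37
  f2 <- extract_transition_features(th)
  expect_equal(f2$t_m_C, f1$t_m_C, tolerance = 1e-12)
  expect_equal(f2$t_half_C, f1$t_half_C, tolerance = 1e-12)
  expect_equal(f2$t_pre_C, f1$t_pre_C, tolerance = 1e-12)
  expect_equal(f2$area, 37 * f1$area, tolerance = 1e-9)
})

test_that("control-vs-treated deltas follow the sign conventions", {
  ctl <- extract_transition_features(gen_thermogram())
  same <- compare_to_control(ctl, ctl)
  expect_equal(same$d_t_m_C, 0)
  expect_equal(same$d_t_half_C, 0)
  expect_false(same$pretransition_suppressed)

  trt <- extract_transition_features(gen_thermogram(
    t_m_C = 39.8, dh_vh_J_mol = vant_hoff_enthalpy_for_fwhm(39.8, 1.2),
    pre_amplitude = 0))
  d <- compare_to_control(ctl, trt)
  expect_equal(d$d_t_m_C, 1.4, tolerance = 0.02 / 1.4)
  expect_equal(d$d_t_half_C, 0.7, tolerance = 0.03 / 0.7)
  expect_true(d$pretransition_suppressed)
})

test_that("thermogram CSV round-trips through the reader", {
  th <- gen_thermogram(pre_amplitude = 0, t_range_C = c(38, 44))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(temperature_C = th$temperature_C,
                       cp_excess = th$cp_excess), f, row.names = FALSE)
  back <- read_thermogram_csv(f)
  expect_equal(back$temperature_C, th$temperature_C)
  expect_equal(back$cp_excess, th$cp_excess)
  expect_error(thermogram(c(1, 2, 3), c(1, 2, 3)), "50")
})
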