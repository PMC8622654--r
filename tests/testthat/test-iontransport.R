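test_that("Boltzmann conversion matches closed-form values", {
  expect_identical(boltzmann_delta_phi(1), 0)
  # kT/e at 298.15 K from physical constants
  expect_equal(thermal_voltage_mV(298.15), 25.693, tolerance = 5e-4 / 25.693)
  expect_equal(boltzmann_delta_phi(exp(1)), -thermal_voltage_mV(298.15))
  # oracle: exp(70 / (kT/e)) inverts to -70 mV
  g <- exp(70 / thermal_voltage_mV(298.15))
  expect_equal(boltzmann_delta_phi(g), -70)
  expect_equal(boltzmann_delta_phi(15.25), -70.0, tolerance = 1e-3)
})

test_that("Boltzmann conversion rejects bad ratios and names the value", {
  expect_error(boltzmann_delta_phi(0), "offending value: 0")
  expect_error(boltzmann_delta_phi(-2), "-2")
  expect_error(boltzmann_delta_phi(NaN), "offending")
  expect_error(conductance_ratio_from_delta_phi(Inf), "finite")
})

test_that("conversion and its inverse round-trip to 1e-12 relative", {
  for (z in c(1L, -1L)) {
    ch <- charge_spec(z)
    for (x in seq(-120, 120, length.out = 9)) {
      back <- boltzmann_delta_phi(
        conductance_ratio_from_delta_phi(x, charge = ch), charge = ch)
      expect_equal(back, x, tolerance = 1e-12)
    }
  }
  # probe valence flips the sign at equal conductance ratio
  expect_equal(boltzmann_delta_phi(3, charge = charge_spec(-1)),
               -boltzmann_delta_phi(3, charge = charge_spec(1)))
})

test_that("titration curves aggregate replicates correctly", {
  pts <- data.frame(replicate = 1,
                    concentration_uM = c(0, 120),
                    conductance_nS = c(10, 152.5))
  cv <- build_titration_curve(pts)
  expect_equal(nrow(cv), 1L)
  expect_equal(cv$delta_phi_mV, -70.0, tolerance = 1e-3)
  expect_equal(cv$sd_mV, 0)
  expect_equal(cv$n, 1L)

  # identical replicates: sd exactly zero, n counted
  pts3 <- do.call(rbind, lapply(1:3, function(r)
    transform(pts, replicate = r)))
  cv3 <- build_titration_curve(pts3)
  expect_equal(cv3$sd_mV, 0)
  expect_equal(cv3$n, 3L)

  # replicate-count bookkeeping on a multi-replicate synthetic titration
  pts5 <- gen_titration(-67, 21, std_concentrations, noise_sd_mV = 2,
                        n_replicates = 5, seed = 11)
  cv5 <- build_titration_curve(pts5)
  expect_true(all(cv5$n == 5L))
  expect_true(all(diff(cv5$concentration_uM) > 0))
})

test_that("titration curves demand a baseline per replicate", {
  pts <- data.frame(replicate = c(1, 2), concentration_uM = c(0, 40),
                    conductance_nS = c(10, 30))
  expect_error(build_titration_curve(pts), "missing baseline.*2")
  pts0 <- data.frame(replicate = 1, concentration_uM = c(0, 40),
                     conductance_nS = c(10, 30))
  expect_error(build_titration_curve(pts0, baseline_nS = c("1" = 0)),
               "baseline conductance")
})

test_that("noiseless Langmuir round trips recover the generator exactly", {
  set.seed(3)
  pairs <- rbind(langmuir_pairs,
                 data.frame(phi_max = runif(4, -120, -10), k = runif(4, 1, 100)))
  for (i in seq_len(nrow(pairs))) {
    pts <- gen_titration(pairs$phi_max[i], pairs$k[i], std_concentrations)
    cv <- build_titration_curve(pts)
    nl <- fit_langmuir_nonlinear(cv)
    expect_equal(nl$phi_max_mV, pairs$phi_max[i], tolerance = 1e-6)
    expect_equal(nl$k_uM, pairs$k[i], tolerance = 1e-6)
    for (mode in c("double_reciprocal", "plateau")) {
      lin <- suppressWarnings(fit_langmuir_linearized(cv, mode))
      expect_equal(lin$phi_max_mV, pairs$phi_max[i], tolerance = 1e-6)
      expect_equal(lin$k_uM, pairs$k[i], tolerance = 1e-6)
      expect_identical(lin$method, "linearized")
    }
  }
})

test_that("the linearized regression has unit intercept on perfect data", {
  C <- std_concentrations
  phi <- -67 * C / (C + 21)
  m <- lm(I(-67 / phi) ~ I(1 / C))
  expect_equal(unname(coef(m)[1]), 1, tolerance = 1e-12)
  expect_equal(unname(coef(m)[2]), 21, tolerance = 1e-9)
})

test_that("Langmuir fitting rejects unusable curves", {
  two <- data.frame(concentration_uM = c(10, 40),
                    delta_phi_mV = c(-20, -40), sd_mV = 0, n = 1)
  expect_error(fit_langmuir_nonlinear(two), "insufficient")
  mixed <- data.frame(concentration_uM = c(5, 40, 120),
                      delta_phi_mV = c(5, -40, -60), sd_mV = 0, n = 1)
  expect_error(fit_langmuir_nonlinear(mixed), "sign")
  zero <- data.frame(concentration_uM = c(5, 40, 120),
                     delta_phi_mV = c(0, -40, -60), sd_mV = 0, n = 1)
  expect_error(fit_langmuir_linearized(zero), "undefined")
})

test_that("linearized and nonlinear K agree on noisy data", {
  pts <- gen_titration(-67, 21, std_concentrations, noise_sd_mV = 3,
                       n_replicates = 5, seed = 99)
  cv <- build_titration_curve(pts)
  nl <- fit_langmuir_nonlinear(cv)
  lin <- fit_langmuir_linearized(cv)
  expect_lt(abs(nl$k_uM - lin$k_uM), 3 * (nl$se_k_uM + lin$se_k_uM))
  # and both sit near the truth
  expect_lt(abs(nl$k_uM - 21), 3 * max(nl$se_k_uM, 1))
})

test_that("Langmuir prediction honours its closed form", {
  fit <- list(phi_max_mV = -67, k_uM = 21)
  expect_equal(langmuir_predict(fit, 0), 0)
  expect_equal(langmuir_predict(fit, 21), -33.5)
  expect_gt(langmuir_predict(fit, 1e6), -67)
  expect_equal(langmuir_predict(fit, 1e6), -67, tolerance = 1e-4)
  expect_error(langmuir_predict(fit, -1), ">= 0")
  # monotone and bounded
  p <- langmuir_predict(fit, seq(0, 500, by = 10))
  expect_true(all(diff(p) < 0))
  expect_true(all(abs(p) < 67))
})

test_that("titration CSV and fit JSON round-trip", {
  pts <- gen_titration(-67, 21, std_concentrations, n_replicates = 2, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(pts, f, row.names = FALSE)
  back <- read_titration_csv(f)
  fit <- fit_langmuir_nonlinear(build_titration_curve(back))
  expect_equal(fit$k_uM, 21, tolerance = 1e-6)
  js <- jsonlite::fromJSON(write_langmuir_json(fit))
  expect_equal(js$K_uM, 21, tolerance = 1e-6)
  expect_identical(js$method, "nonlinear")
  expect_identical(js$n_points, 7L)
})
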