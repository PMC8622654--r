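test_that("all generators are deterministic under a fixed seed", {
  a <- gen_titration(-67, 21, std_concentrations, noise_sd_mV = 3,
                     n_replicates = 3, seed = 50)
  b <- gen_titration(-67, 21, std_concentrations, noise_sd_mV = 3,
                     n_replicates = 3, seed = 50)
  expect_identical(a, b)

  t1 <- gen_single_channel_trace(22, 5, 10, duration_s = 5, seed = 51)
  t2 <- gen_single_channel_trace(22, 5, 10, duration_s = 5, seed = 51)
  expect_identical(t1$samples, t2$samples)

  m1 <- gen_macroscopic_trace(10, 5, 20, 100, 400, noise_sd_pA = 1, seed = 52)
  m2 <- gen_macroscopic_trace(10, 5, 20, 100, 400, noise_sd_pA = 1, seed = 52)
  expect_identical(m1$trace$samples, m2$trace$samples)

  d1 <- gen_thermogram(noise_sd = 0.01, seed = 53)
  d2 <- gen_thermogram(noise_sd = 0.01, seed = 53)
  expect_identical(d1$cp_excess, d2$cp_excess)
})

test_that("titration truth passes through the Boltzmann map at half-saturation", {
  pts <- gen_titration(-67, 21, c(21), baseline_nS = 10)
  g <- pts$conductance_nS[pts$concentration_uM == 21]
  dphi <- boltzmann_delta_phi(g / 10)
  expect_equal(dphi, -33.5, tolerance = 1e-9)
})

test_that("channel traces carry the stated amplitude and gating statistics", {
  tr <- gen_single_channel_trace(22, 5, 10, voltage_mV = 200,
                                 duration_s = 60, noise_sd_pA = 0, seed = 54)
  # open-level amplitude g*V = 4.4 pA: the two density modes sit at 0 and 4.4
  expect_equal(sort(attr(tr, "true_amplitude_pA")), 4.4)
  d <- density(tr$samples, n = 2048)
  modes <- d$x[which(diff(sign(diff(d$y))) == -2) + 1]
  modes <- modes[d$y[which(diff(sign(diff(d$y))) == -2) + 1] > 0.05 * max(d$y)]
  expect_equal(sort(c(min(modes), max(modes))), c(0, 4.4), tolerance = 0.02)

  # event count ~ alternating renewal rate D * ko*kc/(ko+kc)
  expected <- 60 * 5 * 10 / 15
  expect_lt(abs(attr(tr, "n_openings") - expected), 3 * sqrt(expected))

  expect_error(gen_single_channel_trace(22, 5, 10, duration_s = 1),
               "record too short")
  expect_error(gen_single_channel_trace(22, 5, 10, duration_s = 60,
                                        sampling_rate_Hz = 1500),
               "exceed 2")
})

test_that("macroscopic records follow the exponential closed form", {
  rec <- gen_macroscopic_trace(10, 11.1, tau_s = 20, addition_time_s = 100,
                               duration_s = 400)
  fs <- rec$trace$sampling_rate_Hz
  i_at <- function(t) rec$trace$samples[round(t * fs)]
  expect_equal(i_at(50), 10)
  plateau <- 111
  expect_equal(i_at(120), plateau + (10 - plateau) * exp(-1), tolerance = 0.01)
  expect_equal(i_at(399), plateau, tolerance = 0.01)
  expect_error(gen_macroscopic_trace(10, 2, tau_s = 100, addition_time_s = 100,
                                     duration_s = 400),
               "5 \\* tau")
})

test_that("thermogram generator normalizes area and honours its knobs", {
  th <- gen_thermogram(pre_amplitude = 0, dh_cal = 2.5)
  expect_equal(pracma::trapz(th$temperature_C, th$cp_excess), 2.5,
               tolerance = 1e-3)
  expect_equal(nrow(detect_transitions(th)), 1L)
  expect_error(gen_thermogram(pre_t_C = 45, pre_amplitude = 0.1), "below")
})
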