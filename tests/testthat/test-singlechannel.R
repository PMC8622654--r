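test_that("baseline estimation finds the closed level", {
  flat <- current_trace(rep(0, 1000))
  expect_equal(estimate_baseline(flat), 0)
  # majority level wins at 30% open occupancy
  sq <- current_trace(rep(c(rep(0, 70), rep(4.4, 30)), 20))
  expect_equal(estimate_baseline(sq), 0, tolerance = 0.05)
  set.seed(21)
  noisy <- current_trace(rnorm(50000, 1.0, 0.2))
  expect_equal(estimate_baseline(noisy), 1.0, tolerance = 0.02)
})

test_that("idealization of a noiseless square wave is exact", {
  tr <- square_trace(amp_pA = 4.4, dwell_s = 0.01, n_cycles = 10)
  id <- idealize_half_amplitude(tr, expected_amplitude_pA = 4.4,
                                min_duration_s = 0.002, baseline_pA = 0)
  seg <- id$segments
  expect_equal(nrow(seg), 20L)
  expect_equal(unique(seg$duration_s), 0.01)
  expect_equal(seg$level_index, rep(c(0L, 1L), 10))
  expect_equal(seg$start_time_s, seq(0, 0.19, by = 0.01), tolerance = 1e-12)
  expect_equal(seg$mean_amplitude_pA[seg$level_index == 1], rep(4.4, 10),
               tolerance = 1e-12)
  expect_equal(id$baseline_pA, 0, tolerance = 1e-12)
})

test_that("events shorter than the minimum duration are absorbed", {
  x <- c(rep(0, 100), rep(4.4, 50), rep(0, 100))  # 10 ms open at 5 kHz
  x[120:122] <- 0                                  # 0.6 ms closed blip inside
  x[30:32] <- 4.4                                  # 0.6 ms open blip in closed
  tr <- current_trace(x, 5000, 1000)
  id <- idealize_half_amplitude(tr, expected_amplitude_pA = 4.4,
                                min_duration_s = 0.002)
  expect_equal(id$segments$level_index, c(0L, 1L, 0L))
})

test_that("amplitudes below detectability are refused", {
  set.seed(4)
  x <- rnorm(5000, 0, 0.5) + rep(c(0, 1), each = 50)
  tr <- current_trace(x, 5000, 1000)
  expect_error(idealize_half_amplitude(tr, expected_amplitude_pA = 1),
               "detectability")
})

test_that("idealized open probability matches the Markov stationary law", {
  tr <- gen_single_channel_trace(22, open_rate_s = 5, close_rate_s = 10,
                                 duration_s = 60, noise_sd_pA = 0.3, seed = 7)
  id <- idealize_half_amplitude(tr)
  expect_equal(open_probability(id), 1 / 3, tolerance = 0.05)
  # the detector tracks the generator's own occupancy closely
  expect_equal(open_probability(id), attr(tr, "true_open_fraction"),
               tolerance = 0.02)

  # longer record: stationary probability pinned down more tightly
  tr2 <- gen_single_channel_trace(22, 5, 10, duration_s = 600,
                                  noise_sd_pA = 0, seed = 8)
  id2 <- idealize_half_amplitude(tr2)
  expect_lt(abs(open_probability(id2) - 1 / 3), 0.02)
  # dwell-time means approach 1/rate
  seg2 <- id2$segments
  expect_equal(mean(seg2$duration_s[seg2$level_index == 1]), 1 / 10,
               tolerance = 0.15)
  expect_equal(mean(seg2$duration_s[seg2$level_index == 0]), 1 / 5,
               tolerance = 0.15)
})

test_that("event conductances are amplitude over voltage in pS", {
  tr <- square_trace(amp_pA = 4.4, voltage_mV = 200)
  id <- idealize_half_amplitude(tr, 4.4, 0.002, baseline_pA = 0)
  expect_equal(events_to_conductance(id), rep(22, 10), tolerance = 1e-9)
  tr2 <- square_trace(amp_pA = 5.6, voltage_mV = 200)
  id2 <- idealize_half_amplitude(tr2, 5.6, 0.002, baseline_pA = 0)
  expect_equal(events_to_conductance(id2), rep(28, 10), tolerance = 1e-9)
  id$cond <- recording_conditions(voltage_mV = 0)
  expect_error(events_to_conductance(id), "voltage")
})

test_that("G-V curves aggregate per voltage and preserve shape ratios", {
  expect_error(gv_curve(list()), "no voltages")
  one <- gv_curve(list("200" = rep(22, 5)))
  expect_equal(one$g_sd_pS, 0)
  flat <- gv_curve(list("50" = rep(22, 8), "100" = rep(22, 8),
                        "150" = rep(22, 8), "200" = rep(22, 8)))
  expect_equal(flat$g_mean_pS, rep(22, 4))
  expect_equal(flat$voltage_mV, c(50, 100, 150, 200))
  # a uniform conductance increment scales the curve without reshaping it
  ctl <- gv_curve(list("50" = rep(22, 5), "200" = rep(22, 5)))
  trt <- gv_curve(list("50" = rep(28, 5), "200" = rep(28, 5)))
  expect_equal(trt$g_mean_pS / ctl$g_mean_pS, rep(28 / 22, 2))
})

test_that("conductance increments are exact arithmetic", {
  pk <- function(g) structure(list(mean_pS = g), class = "peak_fit")
  expect_equal(conductance_increment(pk(22), pk(22)), 0)
  expect_equal(conductance_increment(pk(22), pk(26)), 100 * 4 / 22)
  expect_equal(conductance_increment(pk(22), pk(28)), 100 * 6 / 22)
  expect_error(conductance_increment(pk(0), pk(26)), "> 0")
})

test_that("trace CSV reader honours the JSON sidecar", {
  tr <- gen_single_channel_trace(22, 5, 10, duration_s = 3, noise_sd_pA = 0.1,
                                 seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  t_s <- (seq_along(tr$samples) - 1) / tr$sampling_rate_Hz
  write.csv(data.frame(time_s = t_s, current_pA = tr$samples), f,
            row.names = FALSE)
  writeLines(jsonlite::toJSON(list(sampling_rate = 5000, filter_cutoff = 1000,
                                   voltage_mV = 200), auto_unbox = TRUE),
             paste0(f, ".json"))
  back <- read_trace_csv(f)
  expect_equal(back$sampling_rate_Hz, 5000)
  expect_equal(back$cond$voltage_mV, 200)
  expect_equal(back$samples, tr$samples)
})
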