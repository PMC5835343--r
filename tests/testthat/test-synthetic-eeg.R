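# slow-response profile so choice-locked activity stays out of S epochs
slow_profile <- function(rt = 5000) {
  agent_profile("controls",
                gamble_weights = list(HF = rep(1 / 6, 6), LF = rep(1 / 6, 6)),
                rt_location_ms = c(HF = rt, LF = rt),
                rt_dispersion = c(HF = 0, LF = 0))
}

test_that("a rendered kernel peaks at its mean latency with zero jitter", {
  tp <- component_template("P3a", "S", +1, width_ms = 60, amplitude_uV = 8,
                           latency_ms = 250, jitter_sd_ms = 0)
  t_ms <- seq(-500, 999, by = 0.25)
  k <- render_component(tp, "controls", "HF", "Cz", t_ms)
  expect_equal(t_ms[which.max(k)], 250)
  expect_equal(max(k), 8)
  # FWHM definition: half maximum at center +/- width/2
  expect_equal(k[which.min(abs(t_ms - 280))], 4, tolerance = 1e-2)

  tp0 <- component_template("P3a", "S", +1, width_ms = 60, amplitude_uV = 0,
                            latency_ms = 250)
  expect_true(all(render_component(tp0, "controls", "HF", "Cz", t_ms) == 0))
})

test_that("negative-polarity kernels point downward", {
  tp <- component_template("N2", "S", -1, width_ms = 40, amplitude_uV = 5,
                           latency_ms = 175, jitter_sd_ms = 0)
  k <- render_component(tp, "controls", "HF", "Fz", seq(0, 500, 1))
  expect_equal(min(k), -5)
})

test_that("extremum latency spread tracks the configured jitter SD", {
  tp <- component_template("P3a", "S", +1, width_ms = 60, amplitude_uV = 8,
                           latency_ms = 250, jitter_sd_ms = 15)
  t_ms <- seq(0, 600, by = 0.5)
  set.seed(41)
  lats <- replicate(1000, {
    k <- render_component(tp, "controls", "HF", "Cz", t_ms,
                          jitter_ms = stats::rnorm(1, 0, tp$jitter_sd_ms))
    t_ms[which.max(k)]
  })
  expect_lt(abs(stats::sd(lats) - 15) / 15, 0.10)
})

test_that("doubling template amplitudes doubles the noiseless average", {
  tr <- simulate_session(pgt_params(n_blocks = 2, trials_per_block = 12),
                         slow_profile(), seed = 2)
  tp1 <- default_templates(jitter_sd_ms = 0)
  tp2 <- lapply(tp1, function(t) { t$amplitude_uV <- 2 * t$amplitude_uV; t })
  e1 <- synthesize_epochs(tr, "controls", tp1, zero_noise(), trigger = "S",
                          seed = 4)
  e2 <- synthesize_epochs(tr, "controls", tp2, zero_noise(), trigger = "S",
                          seed = 4)
  expect_equal(2 * e1$data, e2$data, tolerance = 1e-12)
})

test_that("epoching a noiseless recording recovers the planted kernels", {
  p <- pgt_params(n_blocks = 2, trials_per_block = 1)
  tr <- simulate_session(p, slow_profile(), seed = 6)
  tps <- default_templates(jitter_sd_ms = 0)
  tps <- lapply(tps, function(t) { t$jitter_sd_ms <- 0; t })
  rec <- synthesize_recording(tr, "controls", tps, zero_noise(), seed = 8)
  eps <- epoch_recording(rec, "S")
  expect_equal(dim(eps$data), c(2L, 6L, 1536L))
  for (e in 1:2) {
    for (ch in c("POz", "Fz")) {
      planted <- Reduce(`+`, lapply(
        Filter(function(t) t$trigger == "S", tps),
        function(t) render_component(t, "controls", tr$condition[e], ch,
                                     eps$times_ms)))
      expect_equal(eps$data[e, ch, ], planted, tolerance = 1e-4,
                   ignore_attr = TRUE)
    }
  }
})

test_that("recording synthesis is seed-reproducible and warns on overlap", {
  p <- pgt_params(n_blocks = 2, trials_per_block = 2)
  tr <- simulate_session(p, slow_profile(), seed = 3)
  r1 <- synthesize_recording(tr, "controls", seed = 12)
  r2 <- synthesize_recording(tr, "controls", seed = 12)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)

  fast <- simulate_session(p, slow_profile(rt = 100), seed = 3)
  expect_warning(synthesize_recording(fast, "controls", seed = 1,
                                      noise = zero_noise()),
                 "overlap")
})

test_that("matrix + JSON recordings round-trip exactly at 32-bit precision", {
  p <- pgt_params(n_blocks = 2, trials_per_block = 1)
  tr <- simulate_session(p, slow_profile(), seed = 9)
  rec <- synthesize_recording(tr, "controls", seed = 10)
  d1 <- file.path(tempdir(), "rec1"); d2 <- file.path(tempdir(), "rec2")
  write_recording(rec, d1)
  back <- read_recording(d1)
  expect_equal(back$data, rec$data, tolerance = 1e-5)  # float32 quantization
  expect_equal(back$fs, rec$fs)
  expect_identical(back$channels, rec$channels)
  expect_equal(back$events$onset_s, rec$events$onset_s, tolerance = 1e-9)
  # a second round trip is lossless: quantization happens once
  write_recording(back, d2)
  expect_identical(read_recording(d2)$data, back$data)
})

test_that("an empty event list writes and reads back as a valid recording", {
  rec <- structure(list(data = matrix(stats::rnorm(6 * 100), 6,
                                      dimnames = list(electrode_layout(), NULL)),
                        fs = 1024, channels = electrode_layout(),
                        events = data.frame(onset_s = numeric(0),
                                            trigger = character(0),
                                            condition = character(0))),
                   class = "eeg_recording")
  d <- file.path(tempdir(), "rec_empty")
  write_recording(rec, d)
  back <- read_recording(d)
  expect_equal(nrow(back$events), 0L)
  expect_equal(dim(back$data), dim(rec$data))
})

test_that("epoch noise power matches the configured model within 20%", {
  tr <- simulate_session(pgt_params(n_blocks = 2, trials_per_block = 50),
                         slow_profile(), seed = 5)
  nm <- noise_model(blink_rate_per_min = 0, muscle_burst_rate_per_min = 0)
  ep <- synthesize_epochs(tr, "controls", templates = list(), noise = nm,
                          trigger = "S", seed = 13)
  for (ch in c("POz", "Fz")) {
    w_alpha <- c(POz = 1, Fz = 0.3)[[ch]]
    expected <- nm$pink_noise_scale_uV^2 +
      (nm$alpha_amp_uV * w_alpha)^2 / 2 + nm$sensor_sd_uV^2
    observed <- mean(apply(ep$data[, ch, ], 1L, stats::var))
    expect_lt(abs(observed - expected) / expected, 0.20)
  }
})

test_that("a condition-gain on N500 confines the difference wave to its support", {
  tr <- simulate_session(pgt_params(), slow_profile(), seed = 7)
  n500 <- component_template("N500", "S", -1, width_ms = 150,
                             amplitude_uV = c(POz = 1, Pz = 1.5, CPz = 2,
                                              Cz = 3, FCz = 3.5, Fz = 4),
                             latency_ms = 490, jitter_sd_ms = 0,
                             condition_gain = list(
                               controls = list(HF = 1.4, LF = 0.8)))
  ep <- synthesize_epochs(tr, "controls", list(n500), zero_noise(),
                          trigger = "S", seed = 14)
  w <- erp_from_epochs(ep, "P", "controls", filter_stage = "none")
  dw <- difference_wave(w$HF, w$LF)
  support <- dw$times_ms > 490 - 4 * 150 / 2.355 & dw$times_ms < 490 + 4 * 150 / 2.355
  expect_lt(max(abs(dw$curve["Fz", !support])), 0.01)
  # inside the support the planted effect is (1.4 - 0.8) * 4 uV at the peak
  peak_idx <- which.min(abs(dw$times_ms - 490))
  expect_equal(unname(dw$curve["Fz", peak_idx]), 0.6 * -4, tolerance = 0.01)
})
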