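test_that("band-pass keeps 5 Hz, blocks DC, and attenuates 100 Hz by 20 dB", {
  fs <- 1024
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  core <- seq(fs, 3 * fs)  # avoid filtfilt edge transients

  s5 <- sin(2 * pi * 5 * t)
  out5 <- bandpass(s5, fs)
  expect_lt(abs(max(abs(out5[core])) - 1), 0.05)

  s100 <- sin(2 * pi * 100 * t)
  out100 <- bandpass(s100, fs)
  atten_db <- -20 * log10(max(abs(out100[core])))
  expect_gte(atten_db, 20)

  const <- rep(3, length(t))
  expect_lt(max(abs(bandpass(const, fs)[core])), 1e-6 * 3)

  expect_error(bandpass(s5, fs = 50), "too low")
})

test_that("epoching yields the right counts, window and labels", {
  p <- pgt_params(n_blocks = 2, trials_per_block = 2)
  prof <- agent_profile("controls",
                        gamble_weights = list(HF = rep(1/6, 6), LF = rep(1/6, 6)),
                        rt_location_ms = c(HF = 3000, LF = 3000),
                        rt_dispersion = c(HF = 0, LF = 0))
  tr <- simulate_session(p, prof, seed = 15)
  rec <- synthesize_recording(tr, "controls", noise = zero_noise(), seed = 16)
  epS <- epoch_recording(rec, "S")
  epI <- epoch_recording(rec, "I")
  expect_equal(dim(epS$data)[1] + dim(epI$data)[1], 2L * nrow(tr))
  expect_equal(dim(epS$data)[3], 1536L)  # 1.5 s at 1024 Hz
  expect_equal(epS$condition, tr$condition)
  expect_equal(sum(epS$times_ms < 0), 512L)
  expect_equal(epS$times_ms[513], 0)     # trigger sample is t = 0
  expect_lt(max(epS$times_ms), 1000)     # half-open window

  # an event too close to the edge is skipped with a warning
  rec2 <- rec
  rec2$events <- rbind(rec2$events,
                       data.frame(onset_s = 0.1, trigger = "S", condition = "HF"))
  expect_warning(ep2 <- epoch_recording(rec2, "S"), "skipped")
  expect_equal(dim(ep2$data)[1], dim(epS$data)[1])

  rec$events <- rec$events[0, ]
  expect_equal(dim(epoch_recording(rec, "S")$data)[1], 0L)
})

test_that("baseline correction zeroes the pre-trigger mean", {
  t_n <- 1536
  arr <- array(7, dim = c(3, 2, t_n))
  ep <- make_epochs(arr)
  bc <- baseline_correct(ep)
  expect_true(all(bc$data == 0))

  # step from 0 to 5 at the trigger
  step <- array(0, dim = c(1, 1, t_n))
  step[1, 1, ep$times_ms >= 0] <- 5
  bs <- baseline_correct(make_epochs(step))
  expect_true(all(bs$data[1, 1, bs$times_ms < 0] == 0))
  expect_true(all(bs$data[1, 1, bs$times_ms >= 0] == 5))

  set.seed(51)
  rnd <- array(stats::rnorm(10 * 3 * t_n), dim = c(10, 3, t_n))
  br <- baseline_correct(make_epochs(rnd))
  base_means <- apply(br$data[, , br$times_ms < 0], c(1, 2), mean)
  expect_lt(max(abs(base_means)), 1e-9)
})

test_that("artifact rejection flags blinks by rule and is monotone", {
  tr <- simulate_session(pgt_params(n_blocks = 2, trials_per_block = 10),
                         default_agent_profiles()$controls, seed = 17)
  ep <- synthesize_epochs(tr, "controls",
                          noise = noise_model(blink_rate_per_min = 0,
                                              muscle_burst_rate_per_min = 0),
                          trigger = "S", seed = 18)
  ep <- baseline_correct(ep)
  clean <- reject_artifacts(ep)
  expect_false(any(clean$rejected))  # clean synthetic epochs are retained

  # plant a 300 uV blink in epoch 3
  ep2 <- ep
  ep2$data[3, , ] <- ep2$data[3, , ] +
    rep(bump(ep$times_ms, 100, 120, 300), each = dim(ep2$data)[2])
  flagged <- reject_artifacts(ep2)
  expect_true(flagged$rejected[3])
  expect_identical(flagged$reject_reason[3], "p2p")

  # retained count is monotone non-decreasing in the p2p limit
  retained <- vapply(c(20, 50, 100, 200, 500), function(lim)
    sum(!reject_artifacts(ep2, p2p_max = lim)$rejected), numeric(1))
  expect_true(all(diff(retained) >= 0))
})

test_that("averaging requires more than twenty usable epochs", {
  t_n <- 1536
  one <- array(stats::rnorm(t_n), dim = c(1, 1, t_n))
  arr21 <- array(rep(one, each = 21), dim = c(21, 1, t_n))
  ep21 <- make_epochs(arr21, condition = rep("HF", 21))
  w <- erp_average(ep21, "HF", "P", "controls")
  expect_equal(w$n_epochs, 21L)
  expect_equal(as.numeric(w$mean), as.numeric(one[1, 1, ]))

  ep20 <- make_epochs(arr21[1:20, , , drop = FALSE], condition = rep("HF", 20))
  expect_error(erp_average(ep20, "HF", "P", "controls"), "20 usable epochs")

  # linearity: the mean of epochs equals the mean of per-epoch means
  set.seed(52)
  arr <- array(stats::rnorm(25 * 2 * t_n), dim = c(25, 2, t_n))
  epr <- make_epochs(arr, condition = rep("HF", 25))
  w2 <- erp_average(epr, "HF")
  expect_equal(w2$mean[1, ], colMeans(arr[, 1, ]), ignore_attr = TRUE)
})

test_that("filtering per epoch and filtering the average give the same ERP", {
  tr <- simulate_session(pgt_params(n_blocks = 2, trials_per_block = 24),
                         default_agent_profiles()$controls, seed = 19)
  ep <- synthesize_epochs(tr, "controls",
                          noise = noise_model(blink_rate_per_min = 0,
                                              muscle_burst_rate_per_min = 0),
                          trigger = "S", seed = 20,
                          channels = c("Fz", "POz"))
  w_epoch <- erp_from_epochs(ep, "P", "controls", filter_stage = "epoch")
  w_avg <- erp_from_epochs(ep, "P", "controls", filter_stage = "average")
  # linear operations commute; differences reduce to the filter's response
  # to the baseline offset, which is small away from the epoch edges
  core <- ep$times_ms > -400 & ep$times_ms < 900
  dev <- max(abs(w_epoch$HF$mean[, core] - w_avg$HF$mean[, core]))
  expect_lt(dev, 0.1)
  amp <- diff(range(w_avg$HF$mean[, core]))
  expect_lt(dev / amp, 0.02)
})

test_that("the pipeline recovers planted templates on noiseless data", {
  tr <- simulate_session(pgt_params(n_blocks = 2, trials_per_block = 24),
                         default_agent_profiles()$controls, seed = 21)
  tps <- lapply(default_templates(), function(t) { t$jitter_sd_ms <- 0; t })
  ep <- synthesize_epochs(tr, "controls", tps, zero_noise(),
                          trigger = "S", seed = 22)
  w <- erp_from_epochs(ep, "P", "controls", filter_stage = "average")
  planted <- Reduce(`+`, lapply(
    Filter(function(t) t$trigger == "S", tps),
    function(t) render_component(t, "controls", "HF", "Cz", ep$times_ms)))
  got <- w$HF$mean["Cz", ]
  # the 0.1-30 Hz band-pass distorts the waveform slightly; shape and peak
  # position must survive
  expect_gt(stats::cor(got, planted), 0.99)
  expect_lt(abs(ep$times_ms[which.max(got)] - ep$times_ms[which.max(planted)]),
            3)
})

test_that("epoch sets and ERP waveforms round-trip through disk bundles", {
  tr <- simulate_session(pgt_params(n_blocks = 2, trials_per_block = 12),
                         default_agent_profiles()$controls, seed = 23)
  ep <- synthesize_epochs(tr, "controls", trigger = "S", seed = 24,
                          channels = c("Fz", "POz"))
  ep <- reject_artifacts(baseline_correct(ep))
  d1 <- file.path(tempdir(), "ep_bundle")
  write_epochs(ep, d1)
  back <- read_epochs(d1)
  expect_equal(back$data, ep$data, tolerance = 1e-5)
  expect_identical(back$condition, ep$condition)
  expect_identical(back$rejected, ep$rejected)
  expect_equal(back$times_ms, ep$times_ms)

  w <- erp_average(ep, "HF", "P01", "controls", min_epochs = 5)
  d2 <- file.path(tempdir(), "erp_bundle")
  write_erp(w, d2)
  w2 <- read_erp(d2)
  expect_equal(w2$mean, w$mean, tolerance = 1e-5)
  expect_identical(w2$n_epochs, w$n_epochs)
  expect_identical(w2$condition, "HF")
  expect_equal(w2$times_ms, w$times_ms)
})
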