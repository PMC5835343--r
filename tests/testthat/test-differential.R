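test_that("difference waves subtract LF from HF pointwise", {
  t_ms <- gamblerp:::epoch_time_grid(1024)
  x <- rbind(bump(t_ms, 250, 60, 8), bump(t_ms, 490, 150, -4))
  hf <- make_erp(x, channels = c("Cz", "Fz"), condition = "HF")
  lf <- make_erp(x, channels = c("Cz", "Fz"), condition = "LF")
  expect_true(all(difference_wave(hf, lf)$curve == 0))

  hf3 <- make_erp(x + 3, channels = c("Cz", "Fz"), condition = "HF")
  expect_equal(max(abs(difference_wave(hf3, lf)$curve - 3)), 0,
               tolerance = 1e-12)

  short <- make_erp(x[, 1:768], fs = 1024, window_ms = c(-500, 250),
                    channels = c("Cz", "Fz"))
  expect_error(difference_wave(short, lf), "mismatch")
})

test_that("group bands have SEM half-width and shrink as 1/sqrt(n)", {
  t_ms <- gamblerp:::epoch_time_grid(1024)
  c1 <- bump(t_ms, 250, 60, 4)

  same <- lapply(1:4, function(i) make_diff(c1, channels = "Cz"))
  b <- group_band(same, "Cz")
  expect_equal(b$lower_curve, b$mean_curve)
  expect_equal(b$upper_curve, b$mean_curve)

  pm <- list(make_diff(c1, channels = "Cz"), make_diff(-c1, channels = "Cz"))
  b2 <- group_band(pm, "Cz")
  expect_equal(max(abs(b2$mean_curve)), 0)
  # for curves c and -c: sample SD = |c| sqrt(2), so SEM = |c|
  expect_equal(b2$upper_curve, abs(c1), tolerance = 1e-12)

  expect_error(group_band(same[1], "Cz"), "at least 2")

  # half-width scales as 1/sqrt(n) for iid curves
  set.seed(71)
  mk <- function(n) lapply(seq_len(n), function(i)
    make_diff(stats::rnorm(length(t_ms)), channels = "Cz"))
  hw <- function(n, reps = 20) mean(replicate(reps, {
    b <- group_band(mk(n), "Cz")
    mean(b$upper_curve - b$mean_curve)
  }))
  ratio <- hw(8) / hw(32)
  expect_lt(abs(ratio - 2), 0.2)
})

test_that("band separation has closed-form and symmetry properties", {
  t_ms <- gamblerp:::epoch_time_grid(1024)
  c1 <- bump(t_ms, 250, 60, 4)

  # identical groups: complete overlap, zero statistic
  g <- lapply(1:5, function(i) make_diff(c1 * i / 5, channels = "Cz"))
  bA <- group_band(g, "Cz"); bB <- group_band(g, "Cz")
  expect_equal(band_separation(bA, bB, c(0, 500))$statistic, 0)

  # zero-width bands a constant k apart integrate to k * W
  z1 <- lapply(1:3, function(i) make_diff(rep(2, length(t_ms)), channels = "Cz"))
  z2 <- lapply(1:3, function(i) make_diff(rep(-1, length(t_ms)), channels = "Cz"))
  b1 <- group_band(z1, "Cz"); b2 <- group_band(z2, "Cz")
  win <- c(100, 300)
  sep <- band_separation(b1, b2, win)$statistic
  w_eff <- diff(range(t_ms[t_ms >= 100 & t_ms <= 300]))  # grid-snapped width
  expect_equal(sep, 3 * w_eff, tolerance = 1e-9)
  # antisymmetry
  expect_equal(band_separation(b2, b1, win)$statistic, -sep)

  # the statistic never exceeds the integrated mean distance
  set.seed(72)
  r1 <- lapply(1:6, function(i) make_diff(stats::rnorm(length(t_ms), 1, 1),
                                          channels = "Cz"))
  r2 <- lapply(1:6, function(i) make_diff(stats::rnorm(length(t_ms), -1, 1),
                                          channels = "Cz"))
  bb1 <- group_band(r1, "Cz"); bb2 <- group_band(r2, "Cz")
  idx <- t_ms >= 100 & t_ms <= 300
  bound <- pracma::trapz(t_ms[idx],
                         abs(bb1$mean_curve - bb2$mean_curve)[idx])
  expect_lte(abs(band_separation(bb1, bb2, win)$statistic), bound)

  expect_error(band_separation(bb1, bb2, c(900, 1200)), "outside")
})

test_that("window amplitude profile integrates planted effects exactly", {
  t_ms <- gamblerp:::epoch_time_grid(1024)

  zero <- lapply(1:6, function(i)
    make_diff(rbind(rep(0, length(t_ms)), rep(0, length(t_ms))),
              channels = c("Fz", "POz")))
  prof0 <- window_amplitude_profile(zero, c(200, 300), n_boot = 200, seed = 3)
  expect_true(all(prof0$mean == 0))
  expect_true(all(prof0$ci_low == 0 & prof0$ci_high == 0))
  expect_true(all(!prof0$significant_nonzero))
  expect_true(all(prof0$degenerate))

  # constant +2 uV over a 100 ms window -> 200 uV*ms per participant
  const <- lapply(1:6, function(i)
    make_diff(rbind(rep(2, length(t_ms)), rep(0, length(t_ms))),
              channels = c("Fz", "POz")))
  prof <- window_amplitude_profile(const, c(200, 300), n_boot = 200, seed = 3)
  fz <- prof[prof$electrode == "Fz", ]
  w_eff <- diff(range(t_ms[t_ms >= 200 & t_ms <= 300]))
  expect_equal(fz$mean, 2 * w_eff, tolerance = 1e-9)
  expect_true(fz$significant_nonzero)
  expect_false(prof$significant_nonzero[prof$electrode == "POz"])

  expect_error(window_amplitude_profile(const[1:3], c(200, 300)), "at least 5")
})

test_that("permutation test is calibrated under exchangeable groups", {
  t_ms <- gamblerp:::epoch_time_grid(1024)
  set.seed(73)
  mk <- function() make_diff(stats::rnorm(length(t_ms), 0, 2), channels = "Cz")
  dA <- lapply(1:8, function(i) mk())
  dB <- lapply(1:8, function(i) mk())
  res <- band_separation_test(dA, dB, "Cz", c(100, 400), n_perm = 99, seed = 4)
  expect_gte(res$p_value, 0.05)  # same distribution: no separation signal
  expect_true(abs(res$statistic) < 200)
})

test_that("default analysis windows carry the documented centers", {
  ws <- analysis_windows("S")
  expect_equal(ws$center_ms, c(80, 260, 490))
  wi <- analysis_windows("I")
  expect_equal(wi$center_ms, c(-450, -140, 490, 850))
  expect_true(all(ws$half_width_ms == 50))
})

test_that("band curve tables stack groups and electrodes in long form", {
  t_ms <- gamblerp:::epoch_time_grid(1024)
  mk <- function(k) make_diff(rbind(k * bump(t_ms, 250, 60, 2), 0 * t_ms),
                              channels = c("Fz", "POz"))
  tab <- band_curve_table(list(controls = list(mk(1), mk(2), mk(3)),
                               ADHD = list(mk(-1), mk(-2), mk(-3))))
  expect_equal(nrow(tab), 2 * 2 * length(t_ms))
  expect_true(all(tab$lower_uV <= tab$mean_uV & tab$mean_uV <= tab$upper_uV))
  fz_c <- tab[tab$group == "controls" & tab$electrode == "Fz", ]
  expect_equal(fz_c$mean_uV, 2 * bump(t_ms, 250, 60, 2))
})
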