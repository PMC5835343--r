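#' Background-noise model for synthetic EEG
#'
#' Additive noise components: 1/f ("pink") background, posterior-weighted
#' alpha oscillation, frontally weighted eye blinks, broadband muscle bursts,
#' and white sensor noise. All magnitudes in microvolts; rates per minute.
#' [zero_noise()] returns a silent model (useful for exact round-trip tests).
#'
#' @param pink_noise_scale_uV RMS of the 1/f background.
#' @param alpha_amp_uV Peak amplitude of the alpha oscillation at POz.
#' @param alpha_freq_hz Alpha frequency.
#' @param blink_rate_per_min Expected blink count per minute.
#' @param blink_amp_uV Blink peak amplitude at Fz (tapers posteriorly).
#' @param muscle_burst_rate_per_min Expected muscle-burst count per minute.
#' @param muscle_amp_uV Within-burst noise SD.
#' @param sensor_sd_uV White sensor-noise SD.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(pink_noise_scale_uV = 10,
                        alpha_amp_uV = 8,
                        alpha_freq_hz = 10,
                        blink_rate_per_min = 10,
                        blink_amp_uV = 150,
                        muscle_burst_rate_per_min = 2,
                        muscle_amp_uV = 25,
                        sensor_sd_uV = 2) {
  vals <- c(pink_noise_scale_uV, alpha_amp_uV, alpha_freq_hz,
            blink_rate_per_min, blink_amp_uV, muscle_burst_rate_per_min,
            muscle_amp_uV, sensor_sd_uV)
  stopifnot(all(vals >= 0))
  structure(list(
    pink_noise_scale_uV = pink_noise_scale_uV,
    alpha_amp_uV = alpha_amp_uV, alpha_freq_hz = alpha_freq_hz,
    blink_rate_per_min = blink_rate_per_min, blink_amp_uV = blink_amp_uV,
    muscle_burst_rate_per_min = muscle_burst_rate_per_min,
    muscle_amp_uV = muscle_amp_uV, sensor_sd_uV = sensor_sd_uV
  ), class = "noise_model")
}

#' @rdname noise_model
#' @export
zero_noise <- function() {
  noise_model(0, 0, 10, 0, 0, 0, 0, 0)
}

#' 1/f ("pink") background noise
#'
#' Spectrally shaped Gaussian noise with power ~ 1/f above `f_floor` (flat
#' below, bounding low-frequency drift) and a 2-pole roll-off above `f_acq`
#' emulating the acquisition chain's anti-aliasing low-pass (scalp EEG
#' carries little power in the high tens of Hz). Normalized so the expected
#' RMS equals `scale`. `pink_noise_matrix` draws `m` independent columns.
#'
#' @param n Samples per series.
#' @param scale Target RMS (microvolts).
#' @param fs Sampling rate, Hz.
#' @param f_floor Corner frequency below which the spectrum is flat.
#' @param f_acq Acquisition low-pass corner, Hz.
#' @return `pink_noise`: numeric vector; `pink_noise_matrix`: n x m matrix.
#' @export
pink_noise <- function(n, scale, fs, f_floor = 0.5, f_acq = 60) {
  pink_noise_matrix(n, 1L, scale, fs, f_floor, f_acq)[, 1L]
}

#' @rdname pink_noise
#' @param m Number of independent series (columns).
#' @export
pink_noise_matrix <- function(n, m, scale, fs, f_floor = 0.5, f_acq = 60) {
  if (scale == 0) return(matrix(0, n, m))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency magnitude
  h <- 1 / sqrt(pmax(f, f_floor)) / sqrt(1 + (f / f_acq)^4)
  h[1] <- 0                                  # remove DC
  h <- h / sqrt(mean(h^2))                   # unit output variance
  w <- matrix(stats::rnorm(n * m), n, m)
  x <- Re(stats::mvfft(stats::mvfft(w) * h, inverse = TRUE)) / n
  scale * x
}

epoch_time_grid <- function(fs, window_ms = c(-500, 1000)) {
  pre <- round(-window_ms[1] / 1000 * fs)
  n <- round(diff(window_ms) / 1000 * fs)
  (seq_len(n) - 1 - pre) / fs * 1000
}

# draw per-epoch artifact occurrences (shared across channels)
draw_epoch_artifacts <- function(n_epochs, dur_s, noise) {
  p_blink <- min(1, noise$blink_rate_per_min * dur_s / 60)
  p_musc <- min(1, noise$muscle_burst_rate_per_min * dur_s / 60)
  list(
    blink = stats::runif(n_epochs) < p_blink,
    blink_t = stats::runif(n_epochs),   # fractional position in the epoch
    muscle = stats::runif(n_epochs) < p_musc,
    muscle_t = stats::runif(n_epochs)
  )
}

blink_kernel <- function(t_ms, center_ms, amp) {
  sigma <- 120 / (2 * sqrt(2 * log(2)))  # 120 ms FWHM
  amp * exp(-((t_ms - center_ms)^2) / (2 * sigma^2))
}

#' Synthesize epoch stacks directly for one participant
#'
#' Fast path of the generator: renders each trial's epoch (window
#' -500..+1000 ms around the requested trigger) as the sum of the planted
#' component kernels plus noise, without building the continuous recording.
#' Per-trial latency jitter of a component is shared across electrodes
#' (a single underlying source). Seed-reproducible.
#'
#' @param trials Trial log from [simulate_session()].
#' @param group `"controls"` or `"ADHD"`.
#' @param templates Component templates ([default_templates()]).
#' @param noise A [noise_model()].
#' @param fs Sampling rate, Hz (default 1024).
#' @param channels Electrode subset (default all six midline sites).
#' @param trigger `"S"` or `"I"`.
#' @param seed Integer seed.
#' @param window_ms Epoch window (half-open), ms relative to the trigger.
#' @return An `epoch_set`: list with `data` (epoch x channel x time array,
#'   microvolts), `fs`, `trigger`, `condition`, `channels`, `times_ms`,
#'   `window_ms`, `rejected`, `reject_reason`.
#' @export
synthesize_epochs <- function(trials, group, templates = default_templates(),
                              noise = noise_model(), fs = 1024,
                              channels = electrode_layout(),
                              trigger = "S", seed = 1,
                              window_ms = c(-500, 1000)) {
  set.seed(as.integer(seed) %% 2147483647L)
  n_ep <- nrow(trials)
  t_ms <- epoch_time_grid(fs, window_ms)
  n_t <- length(t_ms)
  cond <- trials$condition
  tset <- Filter(function(tp) tp$trigger == trigger, templates)
  # per-epoch jitter per component, shared across channels
  jitters <- lapply(tset, function(tp) stats::rnorm(n_ep, 0, tp$jitter_sd_ms))
  art <- draw_epoch_artifacts(n_ep, diff(window_ms) / 1000, noise)
  alpha_phase <- stats::runif(n_ep, 0, 2 * pi)
  dat <- array(0, dim = c(n_ep, length(channels), n_t),
               dimnames = list(NULL, channels, NULL))
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    sig <- matrix(0, n_t, n_ep)
    for (k in seq_along(tset)) {
      tp <- tset[[k]]
      amp0 <- tp$amplitude_uV[[ch]]
      if (amp0 == 0) next
      sigma <- tp$width_ms / (2 * sqrt(2 * log(2)))
      lat <- vapply(seq_len(n_ep), function(e)
        template_latency(tp, group, cond[e], ch), numeric(1)) + jitters[[k]]
      gain <- vapply(cond, function(cd) template_gain(tp, group, cd), numeric(1))
      bump <- exp(-(outer(t_ms, lat, "-")^2) / (2 * sigma^2))
      sig <- sig + bump * rep(amp0 * tp$polarity * gain, each = n_t)
    }
    sig <- sig + pink_noise_matrix(n_t, n_ep, noise$pink_noise_scale_uV, fs)
    if (noise$alpha_amp_uV > 0) {
      a <- noise$alpha_amp_uV * ALPHA_WEIGHTS[[ch]]
      sig <- sig + a * sin(outer(t_ms / 1000 * 2 * pi * noise$alpha_freq_hz,
                                 alpha_phase, "+"))
    }
    if (noise$blink_amp_uV > 0 && any(art$blink)) {
      for (e in which(art$blink)) {
        ctr <- window_ms[1] + art$blink_t[e] * diff(window_ms)
        sig[, e] <- sig[, e] +
          blink_kernel(t_ms, ctr, noise$blink_amp_uV * BLINK_WEIGHTS[[ch]])
      }
    }
    if (noise$muscle_amp_uV > 0 && any(art$muscle)) {
      for (e in which(art$muscle)) {
        ctr <- window_ms[1] + art$muscle_t[e] * diff(window_ms)
        env <- exp(-((t_ms - ctr)^2) / (2 * 60^2))
        sig[, e] <- sig[, e] + noise$muscle_amp_uV * env * stats::rnorm(n_t)
      }
    }
    if (noise$sensor_sd_uV > 0) {
      sig <- sig + stats::rnorm(n_t * n_ep, 0, noise$sensor_sd_uV)
    }
    dat[, ci, ] <- t(sig)
  }
  structure(list(
    data = dat, fs = fs, trigger = trigger, condition = cond,
    channels = channels, times_ms = t_ms, window_ms = window_ms,
    rejected = rep(FALSE, n_ep), reject_reason = rep(NA_character_, n_ep)
  ), class = "epoch_set")
}

#' Synthesize a continuous multichannel EEG recording
#'
#' Renders the whole session on a continuous sample grid: each planted
#' component kernel is added around its trial's S or I marker, on top of 1/f
#' background, alpha, blinks, muscle bursts and sensor noise. The event list
#' carries (time, trigger, condition) for every marker. Seed-reproducible.
#' A warning is issued for trials whose S-I interval is under 500 ms
#' (overlapping epochs); they are still rendered.
#'
#' @inheritParams synthesize_epochs
#' @return An `eeg_recording`: list with `data` (channel x sample matrix,
#'   microvolts), `fs`, `channels`, `events` (data.frame `onset_s`,
#'   `trigger`, `condition`).
#' @export
synthesize_recording <- function(trials, group,
                                 templates = default_templates(),
                                 noise = noise_model(), fs = 1024,
                                 channels = electrode_layout(), seed = 1) {
  set.seed(as.integer(seed) %% 2147483647L)
  if (any(trials$t_I - trials$t_S < 0.5)) {
    warning("some trials have S-I interval < 500 ms; epochs will overlap")
  }
  dur_s <- max(trials$t_I) + 2.5
  n <- ceiling(dur_s * fs)
  n_ep <- nrow(trials)
  events <- data.frame(
    onset_s = c(trials$t_S, trials$t_I),
    trigger = rep(c("S", "I"), each = n_ep),
    condition = rep(trials$condition, 2),
    stringsAsFactors = FALSE
  )
  events <- events[order(events$onset_s), ]
  rownames(events) <- NULL
  jit <- lapply(templates, function(tp) stats::rnorm(n_ep, 0, tp$jitter_sd_ms))
  dat <- matrix(0, length(channels), n, dimnames = list(channels, NULL))
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    sig <- pink_noise(n, noise$pink_noise_scale_uV, fs)
    if (noise$alpha_amp_uV > 0) {
      sig <- sig + noise$alpha_amp_uV * ALPHA_WEIGHTS[[ch]] *
        sin(2 * pi * noise$alpha_freq_hz * (seq_len(n) - 1) / fs +
              stats::runif(1, 0, 2 * pi))
    }
    if (noise$sensor_sd_uV > 0) sig <- sig + stats::rnorm(n, 0, noise$sensor_sd_uV)
    dat[ci, ] <- sig
  }
  # planted kernels (jitter shared across channels; rendered over +/-5 SD)
  for (k in seq_along(templates)) {
    tp <- templates[[k]]
    marker_s <- if (tp$trigger == "S") trials$t_S else trials$t_I
    sigma <- tp$width_ms / (2 * sqrt(2 * log(2)))
    half <- ceiling(5 * sigma / 1000 * fs)
    for (e in seq_len(n_ep)) {
      t0 <- round(marker_s[e] * fs) + 1L
      for (ci in seq_along(channels)) {
        ch <- channels[ci]
        amp0 <- tp$amplitude_uV[[ch]]
        if (amp0 == 0) next
        lat <- template_latency(tp, group, trials$condition[e], ch) + jit[[k]][e]
        c0 <- t0 + round(lat / 1000 * fs)
        idx <- max(1L, c0 - half):min(n, c0 + half)
        t_rel <- (idx - t0) / fs * 1000
        dat[ci, idx] <- dat[ci, idx] +
          amp0 * tp$polarity * template_gain(tp, group, trials$condition[e]) *
          exp(-((t_rel - lat)^2) / (2 * sigma^2))
      }
    }
  }
  # session-level blinks / muscle bursts (Poisson arrivals)
  add_bursts <- function(rate_per_min, fun) {
    n_b <- stats::rpois(1, rate_per_min * dur_s / 60)
    if (n_b == 0) return()
    at <- stats::runif(n_b, 0, dur_s)
    for (b in at) fun(b)
  }
  if (noise$blink_amp_uV > 0) {
    add_bursts(noise$blink_rate_per_min, function(b) {
      c0 <- round(b * fs) + 1L
      half <- round(0.3 * fs)
      idx <- max(1L, c0 - half):min(n, c0 + half)
      t_rel <- (idx - c0) / fs * 1000
      for (ci in seq_along(channels)) {
        dat[ci, idx] <<- dat[ci, idx] +
          blink_kernel(t_rel, 0, noise$blink_amp_uV * BLINK_WEIGHTS[[channels[ci]]])
      }
    })
  }
  if (noise$muscle_amp_uV > 0) {
    add_bursts(noise$muscle_burst_rate_per_min, function(b) {
      c0 <- round(b * fs) + 1L
      half <- round(0.15 * fs)
      idx <- max(1L, c0 - half):min(n, c0 + half)
      env <- exp(-(((idx - c0) / fs * 1000)^2) / (2 * 60^2))
      for (ci in seq_along(channels)) {
        dat[ci, idx] <<- dat[ci, idx] + noise$muscle_amp_uV * env *
          stats::rnorm(length(idx))
      }
    })
  }
  structure(list(data = dat, fs = fs, channels = channels, events = events),
            class = "eeg_recording")
}

#' Write / read a recording as matrix + JSON sidecar
#'
#' On-disk dialect: `data.bin` holds little-endian 32-bit floats, one channel
#' after another (row = channel, column = sample); `recording.json` carries
#' fs, channel names and sample count; `events.tsv` has columns `onset_s`,
#' `trigger`, `condition`. A write-read round trip is exact at 32-bit float
#' precision.
#'
#' @param recording An `eeg_recording`.
#' @param dir Directory to write into (created if missing).
#' @return `read_recording` returns the `eeg_recording`.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(recording$data)), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(fs = recording$fs, channels = recording$channels,
         n_samples = ncol(recording$data)),
    file.path(dir, "recording.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(recording$events, file.path(dir, "events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "recording.json"),
                              simplifyVector = TRUE)
  n_ch <- length(meta$channels)
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n_ch * meta$n_samples, size = 4L,
               endian = "little")
  dat <- matrix(x, nrow = n_ch, byrow = TRUE,
                dimnames = list(meta$channels, NULL))
  events <- utils::read.delim(file.path(dir, "events.tsv"),
                              stringsAsFactors = FALSE)
  structure(list(data = dat, fs = meta$fs, channels = meta$channels,
                 events = events), class = "eeg_recording")
}
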