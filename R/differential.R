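#' Feedback-frequency difference wave
#'
#' Pointwise HF-minus-LF difference of one participant's two condition ERPs
#' (same trigger and time base required).
#'
#' @param erp_HF,erp_LF `erp_waveform`s for the HF and LF conditions.
#' @return A `difference_wave`: list with `curve` (channel x time matrix),
#'   `participant`, `group`, `trigger`, `fs`, `times_ms`, `channels`.
#' @export
difference_wave <- function(erp_HF, erp_LF) {
  stopifnot(inherits(erp_HF, "erp_waveform"), inherits(erp_LF, "erp_waveform"))
  if (!isTRUE(all.equal(erp_HF$times_ms, erp_LF$times_ms)) ||
      !identical(rownames(erp_HF$mean), rownames(erp_LF$mean))) {
    stop("mismatched time base or channels between the two ERPs")
  }
  if (!identical(erp_HF$trigger, erp_LF$trigger)) stop("trigger mismatch")
  structure(list(
    curve = erp_HF$mean - erp_LF$mean,
    participant = erp_HF$participant, group = erp_HF$group,
    trigger = erp_HF$trigger, fs = erp_HF$fs, times_ms = erp_HF$times_ms,
    channels = rownames(erp_HF$mean)
  ), class = "difference_wave")
}

#' Group confidence band of difference waves
#'
#' Pointwise mean curve with a mean -/+ SEM envelope (SEM = sample SD /
#' sqrt(n)) over participants, for one electrode.
#'
#' @param diffs List of `difference_wave`s (one per participant, same group).
#' @param electrode Electrode name.
#' @param group Group label stored on the band (default taken from the first
#'   difference wave).
#' @return A `band_curve`: list with `mean_curve`, `lower_curve`,
#'   `upper_curve`, `n_participants`, `electrode`, `group`, `trigger`,
#'   `times_ms`.
#' @export
group_band <- function(diffs, electrode, group = NULL) {
  n <- length(diffs)
  if (n < 2L) stop("need at least 2 participants to form a band")
  m <- do.call(rbind, lapply(diffs, function(d) d$curve[electrode, ]))
  mu <- colMeans(m)
  sem <- apply(m, 2L, stats::sd) / sqrt(n)
  structure(list(
    mean_curve = mu, lower_curve = mu - sem, upper_curve = mu + sem,
    n_participants = n, electrode = electrode,
    group = if (is.null(group)) diffs[[1]]$group else group,
    trigger = diffs[[1]]$trigger, times_ms = diffs[[1]]$times_ms
  ), class = "band_curve")
}

#' Default integration windows for the differential analysis
#'
#' Window centers for the trial-onset analysis: 80 ms (C1), 260 ms (N2-P3
#' complex) and 490 ms (N500); for the choice-locked analysis: -450 ms and
#' -140 ms (pre-choice activity), +490 ms (N400-like) and +850 ms (LPP).
#' Half-width defaults to 50 ms.
#'
#' @param trigger `"S"` or `"I"`.
#' @param half_width_ms Window half-width, ms.
#' @return Data.frame with `label`, `center_ms`, `half_width_ms`.
#' @export
analysis_windows <- function(trigger = c("S", "I"), half_width_ms = 50) {
  trigger <- match.arg(trigger)
  if (trigger == "S") {
    data.frame(label = c("C1", "N2-P3", "N500"),
               center_ms = c(80, 260, 490),
               half_width_ms = half_width_ms, stringsAsFactors = FALSE)
  } else {
    data.frame(label = c("pre450", "pre140", "N400-like", "LPP"),
               center_ms = c(-450, -140, 490, 850),
               half_width_ms = half_width_ms, stringsAsFactors = FALSE)
  }
}

window_indices <- function(times_ms, window_ms) {
  dt <- times_ms[2] - times_ms[1]
  if (window_ms[1] < min(times_ms) - dt || window_ms[2] > max(times_ms) + dt) {
    stop("integration window outside the epoch range")
  }
  idx <- which(times_ms >= window_ms[1] & times_ms <= window_ms[2])
  if (length(idx) < 2L) stop("integration window outside the epoch range")
  idx
}

#' Integrated band separation between two groups
#'
#' Pointwise signed separation of two confidence bands,
#' `s(t) = max(0, lower_A - upper_B) - max(0, lower_B - upper_A)`
#' (zero wherever the bands overlap), integrated over a time window by the
#' trapezoidal rule. The statistic is antisymmetric in the two groups and is
#' bounded by the integrated distance between the group mean curves.
#'
#' @param band_A,band_B `band_curve`s on a common time base.
#' @param window_ms `c(lo, hi)` in ms.
#' @return List with `statistic` (microvolt-ms), `window_ms`, `electrode`.
#' @export
band_separation <- function(band_A, band_B, window_ms) {
  stopifnot(isTRUE(all.equal(band_A$times_ms, band_B$times_ms)))
  idx <- window_indices(band_A$times_ms, window_ms)
  s <- pmax(0, band_A$lower_curve - band_B$upper_curve) -
    pmax(0, band_B$lower_curve - band_A$upper_curve)
  list(statistic = pracma::trapz(band_A$times_ms[idx], s[idx]),
       window_ms = window_ms, electrode = band_A$electrode)
}

#' Permutation test on the band-separation statistic
#'
#' Re-derives both group bands under random permutations of the group labels
#' across participants and compares the observed integrated separation
#' against the permutation distribution (two-sided).
#'
#' @param diffs_A,diffs_B Lists of `difference_wave`s for the two groups.
#' @param electrode Electrode name.
#' @param window_ms Integration window, ms.
#' @param n_perm Number of permutations (default 500).
#' @param seed Seed for the permutation stream.
#' @return List with `statistic`, `p_value`, `electrode`, `window_ms`,
#'   `n_perm`.
#' @export
band_separation_test <- function(diffs_A, diffs_B, electrode, window_ms,
                                 n_perm = 500L, seed = 1L) {
  obs <- band_separation(group_band(diffs_A, electrode),
                         group_band(diffs_B, electrode), window_ms)$statistic
  all_d <- c(diffs_A, diffs_B)
  nA <- length(diffs_A)
  n <- length(all_d)
  set.seed(as.integer(seed) %% 2147483647L)
  perm_stats <- vapply(seq_len(n_perm), function(i) {
    lab <- sample.int(n, nA)
    band_separation(group_band(all_d[lab], electrode),
                    group_band(all_d[-lab], electrode), window_ms)$statistic
  }, numeric(1))
  p <- (1 + sum(abs(perm_stats) >= abs(obs))) / (n_perm + 1)
  list(statistic = obs, p_value = p, electrode = electrode,
       window_ms = window_ms, n_perm = n_perm)
}

#' Figure-ready long table of group confidence bands
#'
#' Stacks [group_band()] envelopes for several groups and electrodes into a
#' tidy long data.frame (one row per group x electrode x time point),
#' suitable for plotting difference-wave panels.
#'
#' @param diffs_by_group Named list of `difference_wave` lists (one entry
#'   per group).
#' @param electrodes Electrodes to include (default: all in the data).
#' @return Data.frame with `group`, `electrode`, `time_ms`, `mean_uV`,
#'   `lower_uV`, `upper_uV`, `n_participants`.
#' @export
band_curve_table <- function(diffs_by_group, electrodes = NULL) {
  stopifnot(length(diffs_by_group) >= 1, !is.null(names(diffs_by_group)))
  if (is.null(electrodes)) electrodes <- diffs_by_group[[1]][[1]]$channels
  rows <- list()
  for (g in names(diffs_by_group)) {
    for (el in electrodes) {
      b <- group_band(diffs_by_group[[g]], el, group = g)
      rows[[paste(g, el)]] <- data.frame(
        group = g, electrode = el, time_ms = b$times_ms,
        mean_uV = b$mean_curve, lower_uV = b$lower_curve,
        upper_uV = b$upper_curve, n_participants = b$n_participants,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Seeded percentile bootstrap over observations; the same machinery used by
#' [window_amplitude_profile()].
#'
#' @param x Numeric observations.
#' @param n_boot Number of resamples.
#' @param seed Seed.
#' @param conf Confidence level.
#' @return Numeric `c(low, high)`.
#' @export
bootstrap_ci_mean <- function(x, n_boot = 2000L, seed = 1L, conf = 0.95) {
  set.seed(as.integer(seed) %% 2147483647L)
  n <- length(x)
  alpha <- (1 - conf) / 2
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  boot_means <- colMeans(matrix(x[idx], n, n_boot))
  unname(stats::quantile(boot_means, c(alpha, 1 - alpha)))
}

#' Per-electrode window-amplitude profile with bootstrap CIs
#'
#' For each participant the difference curve is integrated (trapezoid) over
#' the window, in microvolt-ms; per electrode the group mean of these
#' integrals is reported with a seeded percentile-bootstrap 95% CI over
#' participants and a flag for CIs excluding zero, plus a Wilcoxon
#' signed-rank test of the integrals against zero. This is the
#' spatial-profile reading of the differential analysis (amplitude of the
#' feedback-related difference per recording site).
#'
#' @param diffs List of `difference_wave`s (one group).
#' @param window_ms Integration window, ms.
#' @param electrodes Electrodes to profile (default: all in the data).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return Data.frame, one row per electrode: `electrode`, `n`, `mean`,
#'   `ci_low`, `ci_high`, `significant_nonzero`, `p_wilcoxon`, `degenerate`.
#' @export
window_amplitude_profile <- function(diffs, window_ms, electrodes = NULL,
                                     n_boot = 2000L, seed = 1L, conf = 0.95) {
  if (length(diffs) < 5L) stop("need at least 5 participants for the bootstrap")
  if (is.null(electrodes)) electrodes <- diffs[[1]]$channels
  t_ms <- diffs[[1]]$times_ms
  idx <- window_indices(t_ms, window_ms)
  n <- length(diffs)
  rows <- lapply(seq_along(electrodes), function(ei) {
    el <- electrodes[ei]
    ints <- vapply(diffs, function(d)
      pracma::trapz(t_ms[idx], d$curve[el, idx]), numeric(1))
    ci <- bootstrap_ci_mean(ints, n_boot, seed = seed + ei - 1L, conf = conf)
    degenerate <- diff(range(ints)) == 0
    p_w <- if (all(ints == 0) || degenerate) 1 else
      wilcoxon_signed(ints)$p_value
    data.frame(
      electrode = el, n = n, mean = mean(ints),
      ci_low = ci[1], ci_high = ci[2],
      significant_nonzero = !(ci[1] <= 0 && 0 <= ci[2]),
      p_wilcoxon = p_w, degenerate = degenerate,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
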