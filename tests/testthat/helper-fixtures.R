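# small constructors used across test files (all fixtures built in code)

# an erp_waveform from a channel x time matrix (or a single-channel vector)
make_erp <- function(x, fs = 1024, window_ms = c(-500, 1000),
                     channels = NULL, condition = "HF", trigger = "S",
                     participant = "P", group = "controls") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  t_ms <- gamblerp:::epoch_time_grid(fs, window_ms)
  stopifnot(ncol(x) == length(t_ms))
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(x)))
  rownames(x) <- channels
  structure(list(mean = x, n_epochs = 30L, participant = participant,
                 group = group, condition = condition, trigger = trigger,
                 fs = fs, times_ms = t_ms),
            class = "erp_waveform")
}

# a difference_wave directly from a channel x time matrix
make_diff <- function(x, fs = 1024, window_ms = c(-500, 1000),
                      channels = NULL, participant = "P",
                      group = "controls", trigger = "S") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  t_ms <- gamblerp:::epoch_time_grid(fs, window_ms)
  stopifnot(ncol(x) == length(t_ms))
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(x)))
  rownames(x) <- channels
  structure(list(curve = x, participant = participant, group = group,
                 trigger = trigger, fs = fs, times_ms = t_ms,
                 channels = channels),
            class = "difference_wave")
}

# an epoch_set from an epoch x channel x time array
make_epochs <- function(arr, fs = 1024, window_ms = c(-500, 1000),
                        condition = NULL, trigger = "S", channels = NULL) {
  n_ep <- dim(arr)[1]
  if (is.null(condition)) condition <- rep("HF", n_ep)
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(arr)[2]))
  dimnames(arr) <- list(NULL, channels, NULL)
  structure(list(data = arr, fs = fs, trigger = trigger,
                 condition = condition, channels = channels,
                 times_ms = gamblerp:::epoch_time_grid(fs, window_ms),
                 window_ms = window_ms,
                 rejected = rep(FALSE, n_ep),
                 reject_reason = rep(NA_character_, n_ep)),
            class = "epoch_set")
}

# a gaussian bump over an epoch time grid
bump <- function(t_ms, center, fwhm, amp) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  amp * exp(-((t_ms - center)^2) / (2 * s^2))
}

# a minimal trial log with given RTs (ms)
rt_trials <- function(rt_ms, condition = "HF") {
  n <- length(rt_ms)
  data.frame(participant_id = "P", block_index = 0L,
             trial_index = seq_len(n) - 1L,
             condition = rep(condition, length.out = n),
             gamble = 8L, won = FALSE, points_after = 12L,
             rt_ms = rt_ms, t_S = seq_len(n) * 10, t_I = seq_len(n) * 10 + rt_ms / 1000,
             stringsAsFactors = FALSE)
}

# brute-force Mann-Whitney oracle: U by pair counting, p by enumerating
# all group assignments of the pooled values
mw_oracle <- function(a, b) {
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(a, b)
  n1 <- length(a)
  mu <- n1 * length(b) / 2
  obs <- u_stat(a, b)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  list(U = obs, p = mean(abs(us - mu) >= abs(obs - mu) - 1e-12))
}
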