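#' Task parameters for the probabilistic gambling task
#'
#' Defines the session design and payoff rule of the modified Gneezy-Potters
#' gambling task: on every trial the player is endowed with a fixed number of
#' points, stakes one of an allowed set of amounts, and either loses the stake
#' (probability `1 - win_probability`) or receives `win_multiplier` times the
#' stake on top of the unstaked remainder. Blocks alternate between
#' high-frequency (`HF`, outcome shown every trial) and low-frequency (`LF`,
#' outcome withheld) feedback.
#'
#' @param endowment Points endowed at the start of every trial.
#' @param allowed_gambles Ordered integer vector of stake values; must lie in
#'   `[0, endowment]`.
#' @param win_probability Probability of winning a gamble, in (0, 1).
#' @param win_multiplier Payout multiplier applied to the stake on a win.
#' @param n_blocks Number of blocks (must be even for balanced conditions).
#' @param trials_per_block Trials per block.
#' @param first_block_condition `"HF"` or `"LF"`; condition of block 0.
#' @param outcome_display_s Seconds the outcome screen is shown after the
#'   choice (used only to place event markers on the session clock).
#' @param inter_trial_gap_s Seconds between the end of one trial and the next
#'   trial-onset marker.
#' @return An object of class `pgt_params`.
#' @export
pgt_params <- function(endowment = 20L,
                       allowed_gambles = c(0L, 4L, 8L, 12L, 16L, 20L),
                       win_probability = 1 / 3,
                       win_multiplier = 4L,
                       n_blocks = 10L,
                       trials_per_block = 16L,
                       first_block_condition = c("HF", "LF"),
                       outcome_display_s = 4,
                       inter_trial_gap_s = 1) {
  first_block_condition <- match.arg(first_block_condition)
  stopifnot(
    endowment > 0,
    win_probability > 0, win_probability < 1,
    all(allowed_gambles >= 0), all(allowed_gambles <= endowment),
    all(allowed_gambles == as.integer(allowed_gambles)),
    n_blocks >= 1, trials_per_block >= 1
  )
  structure(
    list(
      endowment = as.integer(endowment),
      allowed_gambles = as.integer(allowed_gambles),
      win_probability = win_probability,
      win_multiplier = as.integer(win_multiplier),
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      first_block_condition = first_block_condition,
      outcome_display_s = outcome_display_s,
      inter_trial_gap_s = inter_trial_gap_s
    ),
    class = "pgt_params"
  )
}

#' Resolve the payoff of a single gamble
#'
#' Pure payoff rule: a loss leaves `endowment - gamble`; a win returns the
#' unstaked remainder plus `win_multiplier * gamble`. With the default
#' 20-point endowment and multiplier 4, staking 8 yields 12 on a loss and
#' 44 on a win.
#'
#' @param params A [pgt_params()] object.
#' @param gamble Stake, one of `params$allowed_gambles`.
#' @param won Logical; did the lottery come up a win?
#' @return Integer points held after the trial.
#' @export
resolve_trial <- function(params, gamble, won) {
  stopifnot(inherits(params, "pgt_params"), is.logical(won), length(won) == 1L)
  if (!gamble %in% params$allowed_gambles) {
    stop("invalid gamble: ", gamble, " not in {",
         paste(params$allowed_gambles, collapse = ", "), "}")
  }
  base <- params$endowment - as.integer(gamble)
  if (won) base + params$win_multiplier * as.integer(gamble) else base
}

#' Build the block/condition design of a session
#'
#' Conditions strictly alternate by block starting at
#' `params$first_block_condition`.
#'
#' @param params A [pgt_params()] object.
#' @return A data.frame with one row per trial: `block_index` (0-based),
#'   `trial_index` (0-based within session) and `condition`.
#' @export
build_session_design <- function(params) {
  stopifnot(inherits(params, "pgt_params"))
  if (params$n_blocks %% 2L != 0L) {
    stop("n_blocks must be even for balanced HF/LF conditions")
  }
  other <- if (params$first_block_condition == "HF") "LF" else "HF"
  block_cond <- rep(c(params$first_block_condition, other),
                    length.out = params$n_blocks)
  n_trials <- params$n_blocks * params$trials_per_block
  data.frame(
    block_index = rep(seq_len(params$n_blocks) - 1L,
                      each = params$trials_per_block),
    trial_index = seq_len(n_trials) - 1L,
    condition = rep(block_cond, each = params$trials_per_block),
    stringsAsFactors = FALSE
  )
}

#' Behavioral profile of a simulated player
#'
#' Gamble choice is drawn per condition from a categorical distribution over
#' the allowed stakes; response times are drawn from a condition-specific
#' log-normal (right-skewed, strictly positive), truncated to
#' (0, 20000] ms. Default profiles calibrated to the study groups are
#' available via [default_agent_profiles()].
#'
#' @param group `"controls"` or `"ADHD"`.
#' @param gamble_weights Named list with elements `HF` and `LF`, each a
#'   probability vector over the allowed gambles (sums to 1 within 1e-9).
#' @param rt_location_ms Named numeric `c(HF=, LF=)`: median RT in ms
#'   (the log-normal meanlog is `log` of this value).
#' @param rt_dispersion Named numeric `c(HF=, LF=)`: log-normal sdlog.
#' @param seed_offset Integer mixed into the per-participant stream seed.
#' @return An object of class `agent_profile`.
#' @export
agent_profile <- function(group = c("controls", "ADHD"),
                          gamble_weights,
                          rt_location_ms,
                          rt_dispersion = c(HF = 0.45, LF = 0.45),
                          seed_offset = 0L) {
  group <- match.arg(group)
  for (cond in c("HF", "LF")) {
    w <- gamble_weights[[cond]]
    if (abs(sum(w) - 1) > 1e-9) stop("gamble_weights$", cond, " must sum to 1")
    if (any(w < 0)) stop("gamble_weights must be non-negative")
    if (rt_location_ms[[cond]] <= 0) stop("rt_location_ms must be positive")
  }
  structure(
    list(group = group, gamble_weights = gamble_weights,
         rt_location_ms = rt_location_ms, rt_dispersion = rt_dispersion,
         seed_offset = as.integer(seed_offset)),
    class = "agent_profile"
  )
}

#' Default agent profiles for the two study groups
#'
#' Response-time medians follow the group/condition medians observed in the
#' study (controls 1083/1032 ms, ADHD 1544/1274 ms for HF/LF); stake
#' preferences are mildly risk-neutral with the ADHD profile tilted slightly
#' toward high stakes, matching the sign (not magnitude) of the observed risk
#' indices.
#'
#' @param n_gambles Number of allowed stake values (default 6).
#' @return Named list with elements `controls` and `ADHD`.
#' @export
default_agent_profiles <- function(n_gambles = 6L) {
  unif <- rep(1 / n_gambles, n_gambles)
  tilt <- function(delta) {
    w <- unif + delta * seq(-1, 1, length.out = n_gambles) / n_gambles
    w / sum(w)
  }
  list(
    controls = agent_profile(
      group = "controls",
      gamble_weights = list(HF = tilt(0.05), LF = tilt(0)),
      rt_location_ms = c(HF = 1083, LF = 1032)
    ),
    ADHD = agent_profile(
      group = "ADHD",
      gamble_weights = list(HF = tilt(0.25), LF = tilt(0.25)),
      rt_location_ms = c(HF = 1544, LF = 1274)
    )
  )
}

#' Derive a reproducible per-participant stream seed
#'
#' Mixes a master seed with a participant identifier so that participant-level
#' simulation is reproducible independently of simulation order.
#'
#' @param master_seed Integer master seed.
#' @param participant_id Character or integer identifier.
#' @return Integer in `[0, 2^31 - 2]`.
#' @export
participant_seed <- function(master_seed, participant_id) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(master_seed) %% m
  for (code in utf8ToInt(as.character(participant_id))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

#' Simulate one gambling-task session
#'
#' Plays every trial of the session design: a stake is drawn from the
#' profile's condition-specific weights, the lottery resolves as a Bernoulli
#' draw with `params$win_probability`, and the response time is a truncated
#' log-normal draw. Event times for the trial-onset (`S`) and choice (`I`)
#' markers are placed on a session clock with the configured outcome-display
#' and inter-trial intervals. Identical `(params, profile, seed)` gives a
#' byte-identical log.
#'
#' @param params A [pgt_params()] object.
#' @param profile An [agent_profile()] object.
#' @param seed Integer seed for this session's random stream.
#' @param participant_id Identifier copied into the log.
#' @return A data.frame of trial records with columns `participant_id`,
#'   `block_index`, `trial_index`, `condition`, `gamble`, `won`,
#'   `points_after`, `rt_ms`, `t_S`, `t_I`.
#' @export
simulate_session <- function(params, profile, seed,
                             participant_id = "P01") {
  stopifnot(inherits(params, "pgt_params"), inherits(profile, "agent_profile"))
  design <- build_session_design(params)
  n <- nrow(design)
  rng <- local({
    set.seed((as.integer(seed) + profile$seed_offset) %% 2147483647L)
    NULL
  })
  gamble <- integer(n)
  rt_ms <- numeric(n)
  for (cond in c("HF", "LF")) {
    idx <- which(design$condition == cond)
    gamble[idx] <- sample(params$allowed_gambles, length(idx), replace = TRUE,
                          prob = profile$gamble_weights[[cond]])
    r <- stats::rlnorm(length(idx),
                       meanlog = log(profile$rt_location_ms[[cond]]),
                       sdlog = profile$rt_dispersion[[cond]])
    rt_ms[idx] <- pmin(r, 20000)
  }
  won <- stats::runif(n) < params$win_probability
  points_after <- ifelse(won,
                         params$endowment - gamble + params$win_multiplier * gamble,
                         params$endowment - gamble)
  # session clock: S, then choice after rt, then outcome display + gap
  trial_len <- rt_ms / 1000 + params$outcome_display_s + params$inter_trial_gap_s
  t_S <- 1 + c(0, cumsum(trial_len[-n]))
  t_I <- t_S + rt_ms / 1000
  data.frame(
    participant_id = participant_id,
    block_index = design$block_index,
    trial_index = design$trial_index,
    condition = design$condition,
    gamble = gamble,
    won = won,
    points_after = as.integer(points_after),
    rt_ms = rt_ms,
    t_S = t_S,
    t_I = t_I,
    stringsAsFactors = FALSE
  )
}

#' Write / read a trial log
#'
#' Plain CSV, one row per trial, columns exactly the trial-record fields.
#'
#' @param trials Trial-log data.frame from [simulate_session()].
#' @param path File path.
#' @return `read_trial_log` returns the trial-log data.frame.
#' @export
write_trial_log <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$won <- as.logical(df$won)
  df
}
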