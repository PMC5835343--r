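#' Local Outlier Factor scores
#'
#' Density-based outlier scores (Breunig et al. style) for a numeric sample:
#' for each point, the ratio of the average local reachability density of its
#' k nearest neighbours to its own. Scores near 1 indicate inlier density;
#' scores clearly above 1 indicate local outliers. Implemented directly for
#' one-dimensional data (distance = absolute difference).
#'
#' @param x Numeric vector.
#' @param k Neighbourhood size.
#' @return Numeric vector of LOF scores (1 for points in constant regions).
#' @export
lof_scores <- function(x, k) {
  n <- length(x)
  stopifnot(k >= 1, k <= n - 1)
  d <- abs(outer(x, x, "-"))
  diag(d) <- Inf
  ord <- apply(d, 1L, order)          # n x n, columns = per-point neighbour order
  kdist <- numeric(n)
  neigh <- vector("list", n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    kd <- sort(di)[k]
    kdist[i] <- kd
    neigh[[i]] <- which(di <= kd)     # >= k points; handles distance ties
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    nb <- neigh[[i]]
    reach <- pmax(kdist[nb], d[i, nb])
    m <- mean(reach)
    lrd[i] <- if (m == 0) Inf else 1 / m
  }
  lof <- numeric(n)
  for (i in seq_len(n)) {
    nb <- neigh[[i]]
    if (is.infinite(lrd[i])) {
      # point in a zero-distance clump: density equal to neighbours' -> 1
      lof[i] <- if (all(is.infinite(lrd[nb]))) 1 else 0
    } else {
      lof[i] <- mean(lrd[nb]) / lrd[i]
    }
  }
  lof
}

#' Filter response times
#'
#' Two-stage screen used for all RT-based endpoints: (1) hard thresholds
#' discard trials with RT < 250 ms or RT > 10 s; (2) remaining trials are
#' scored by Local Outlier Factor on log(RT) and those with score above
#' `lof_threshold` are discarded as outliers. If fewer than `lof_k + 1`
#' trials survive stage 1 the outlier stage is skipped with a warning.
#'
#' @param trials Trial-log data.frame with an `rt_ms` column.
#' @param rt_min_ms,rt_max_ms Hard thresholds in ms (defaults 250 and 10000).
#' @param lof_k LOF neighbourhood size; the effective k is
#'   `min(lof_k, n - 1)`.
#' @param lof_threshold LOF score above which a trial is an outlier.
#' @return A list with data.frames `retained`, `discarded_threshold`,
#'   `discarded_outlier` (an exhaustive, disjoint partition of `trials`).
#' @export
filter_rts <- function(trials, rt_min_ms = 250, rt_max_ms = 10000,
                       lof_k = 20L, lof_threshold = 1.5) {
  stopifnot(nrow(trials) > 0, "rt_ms" %in% names(trials))
  bad_thr <- trials$rt_ms < rt_min_ms | trials$rt_ms > rt_max_ms
  surv <- trials[!bad_thr, , drop = FALSE]
  disc_thr <- trials[bad_thr, , drop = FALSE]
  k <- min(lof_k, nrow(surv) - 1L)
  if (k < 1L) {
    warning("too few trials after threshold filtering; outlier stage skipped")
    return(list(retained = surv, discarded_threshold = disc_thr,
                discarded_outlier = surv[0, , drop = FALSE]))
  }
  score <- lof_scores(log(surv$rt_ms), k)
  out <- score > lof_threshold
  list(retained = surv[!out, , drop = FALSE],
       discarded_threshold = disc_thr,
       discarded_outlier = surv[out, , drop = FALSE])
}

#' Risk index of a trial set
#'
#' The high-risk fraction HR is the relative number of trials staking 12, 16
#' or 20 points; the low-risk fraction LR covers stakes 0, 4 and 8. The risk
#' index RI = (HR - LR)/(HR + LR) lies in [-1, 1]: -1 for a purely
#' risk-averse player, +1 for purely risk-seeking, ~0 risk-neutral.
#'
#' @param trials Trial-log data.frame (`gamble`, `condition` columns).
#' @param scope `"all"`, `"HF"` or `"LF"` — restrict to one feedback
#'   condition or use all trials.
#' @param high_stakes Stake values counted as high-risk.
#' @return A list of class `risk_summary`: `HR`, `LR`, `RI`, `n`, `scope`.
#' @export
risk_index <- function(trials, scope = c("all", "HF", "LF"),
                       high_stakes = c(12L, 16L, 20L)) {
  scope <- match.arg(scope)
  if (scope != "all") trials <- trials[trials$condition == scope, , drop = FALSE]
  n <- nrow(trials)
  if (n == 0L) stop("undefined risk index: no trials in scope '", scope, "'")
  hr <- mean(trials$gamble %in% high_stakes)
  lr <- 1 - hr
  structure(list(HR = hr, LR = lr, RI = (hr - lr) / (hr + lr),
                 n = n, scope = scope),
            class = "risk_summary")
}

#' Session-level behavioral summary
#'
#' Total gains are the cumulated points held over trials (each trial starts
#' from a fresh endowment, so TotG of a never-gambling player over 160 trials
#' is 160 x 20 = 3200). Gains are computed on all trials by default — points
#' are earned regardless of RT validity — while the discard bookkeeping
#' reflects the RT screen of [filter_rts()].
#'
#' @param trials Trial-log data.frame.
#' @param rt_filter Logical; if `TRUE`, also run [filter_rts()] and report
#'   the retained/discarded counts.
#' @param gains_on `"all"` (default) or `"retained"`: trial set used for the
#'   gain sums.
#' @param ... Passed to [filter_rts()].
#' @return A list of class `session_summary` with `TotG`, `TG_HF`, `TG_LF`,
#'   `n_trials_retained`, `n_discarded_threshold`, `n_discarded_outlier`.
#' @export
session_summary <- function(trials, rt_filter = TRUE, gains_on = c("all", "retained"),
                            ...) {
  gains_on <- match.arg(gains_on)
  n_thr <- 0L; n_out <- 0L; retained <- trials
  if (rt_filter) {
    f <- filter_rts(trials, ...)
    retained <- f$retained
    n_thr <- nrow(f$discarded_threshold)
    n_out <- nrow(f$discarded_outlier)
  }
  g <- if (gains_on == "all") trials else retained
  tg <- function(cond) sum(g$points_after[g$condition == cond])
  structure(list(
    TotG = sum(g$points_after),
    TG_HF = tg("HF"),
    TG_LF = tg("LF"),
    n_trials_retained = nrow(retained),
    n_discarded_threshold = n_thr,
    n_discarded_outlier = n_out
  ), class = "session_summary")
}

#' Per-participant behavioral summary table
#'
#' Applies [session_summary()], [risk_index()] and median retained RT per
#' condition to a multi-participant trial log, mirroring the rows of the
#' study's behavioral performance table.
#'
#' @param trials Combined trial log (multiple `participant_id`s) with a
#'   `group` column or a `groups` named vector.
#' @param groups Optional named character vector `participant_id -> group`.
#' @return A data.frame, one row per participant, with columns `TotG`,
#'   `TG_HF`, `TG_LF`, `RI_all`, `RI_HF`, `RI_LF`, `RT_HF`, `RT_LF` (median
#'   retained RT, ms) and the discard counts.
#' @export
behavior_summary_table <- function(trials, groups = NULL) {
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id, , drop = FALSE]
    f <- filter_rts(tr)
    s <- session_summary(tr)
    med_rt <- function(cond) {
      r <- f$retained$rt_ms[f$retained$condition == cond]
      if (length(r)) stats::median(r) else NA_real_
    }
    grp <- if (!is.null(groups)) unname(groups[[id]])
           else if ("group" %in% names(tr)) tr$group[1] else NA_character_
    data.frame(
      participant_id = id, group = grp,
      TotG = s$TotG, TG_HF = s$TG_HF, TG_LF = s$TG_LF,
      RI_all = risk_index(f$retained, "all")$RI,
      RI_HF = risk_index(f$retained, "HF")$RI,
      RI_LF = risk_index(f$retained, "LF")$RI,
      RT_HF = med_rt("HF"), RT_LF = med_rt("LF"),
      n_trials_retained = s$n_trials_retained,
      n_discarded_threshold = s$n_discarded_threshold,
      n_discarded_outlier = s$n_discarded_outlier,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
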