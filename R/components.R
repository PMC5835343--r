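#' Component search specifications
#'
#' Default peak-search windows bracket the approximate component latencies:
#' N2 [130, 230] ms (negative), P3a [200, 310] ms (positive), P3b
#' [300, 430] ms (positive), and C1 [50, 110] ms (positive, POz/Pz only,
#' trial onset). Windows are configurable; each spec applies to one trigger.
#'
#' @param name Component name.
#' @param polarity `+1` or `-1`.
#' @param search_window_ms `c(lo, hi)` in ms, inside the epoch window.
#' @param trigger `"S"` or `"I"`.
#' @param electrodes Electrode subset the component is sought on.
#' @return `component_spec` object; `default_component_specs()` returns the
#'   standard list for a trigger.
#' @export
component_spec <- function(name, polarity, search_window_ms,
                           trigger = c("S", "I"),
                           electrodes = electrode_layout()) {
  trigger <- match.arg(trigger)
  stopifnot(polarity %in% c(-1, 1),
            length(search_window_ms) == 2L,
            search_window_ms[1] < search_window_ms[2])
  structure(list(name = name, polarity = polarity,
                 search_window_ms = search_window_ms, trigger = trigger,
                 electrodes = electrodes),
            class = "component_spec")
}

#' @rdname component_spec
#' @export
default_component_specs <- function(trigger = c("S", "I")) {
  trigger <- match.arg(trigger)
  specs <- list(
    component_spec("N2", -1, c(130, 230), trigger),
    component_spec("P3a", +1, c(200, 310), trigger),
    component_spec("P3b", +1, c(300, 430), trigger)
  )
  if (trigger == "S") {
    specs <- c(list(component_spec("C1", +1, c(50, 110), "S",
                                   electrodes = c("POz", "Pz"))), specs)
  }
  specs
}

#' Detect a component peak on one electrode
#'
#' The peak is the extremum of the polarity-signed waveform among the local
#' extrema strictly inside the search window (endpoints excluded); ties are
#' broken by the earliest latency. Requiring a local extremum rather than a
#' raw argmax avoids latching onto slow-slope endpoints. If no interior local
#' extremum exists the window-edge extremum is returned with
#' `boundary = TRUE`. Detection is invariant to adding a constant offset.
#'
#' @param erp An `erp_waveform`.
#' @param spec A [component_spec()].
#' @param electrode Electrode name, one of `spec$electrodes`.
#' @return A one-row data.frame: `component`, `electrode`, `latency_ms`,
#'   `amplitude_uV`, `boundary`, `participant`, `group`, `condition`,
#'   `trigger`.
#' @export
detect_peak <- function(erp, spec, electrode) {
  stopifnot(inherits(erp, "erp_waveform"),
            electrode %in% spec$electrodes,
            electrode %in% rownames(erp$mean))
  if (!is.na(erp$trigger) && erp$trigger != spec$trigger) {
    stop("trigger mismatch: waveform is ", erp$trigger, ", spec is ",
         spec$trigger)
  }
  t_ms <- erp$times_ms
  in_win <- which(t_ms >= spec$search_window_ms[1] &
                    t_ms <= spec$search_window_ms[2])
  if (length(in_win) < 3L) stop("search window too narrow for the time grid")
  x <- spec$polarity * erp$mean[electrode, ]
  if (diff(range(x[in_win])) == 0) {
    stop("no peak: waveform is flat inside the ", spec$name, " window")
  }
  interior <- in_win[-c(1L, length(in_win))]
  is_locmax <- x[interior] > x[interior - 1L] & x[interior] >= x[interior + 1L]
  cand <- interior[is_locmax]
  if (length(cand) > 0L) {
    best <- cand[x[cand] == max(x[cand])][1L]  # earliest among ties
    boundary <- FALSE
  } else {
    best <- in_win[x[in_win] == max(x[in_win])][1L]
    boundary <- TRUE
  }
  data.frame(
    component = spec$name, electrode = electrode,
    latency_ms = t_ms[best],
    amplitude_uV = erp$mean[electrode, best],
    boundary = boundary,
    participant = erp$participant, group = erp$group,
    condition = erp$condition, trigger = erp$trigger,
    stringsAsFactors = FALSE
  )
}

#' Detect all specified components on all electrodes of a waveform
#'
#' Runs [detect_peak()] for every (spec, electrode) pair and checks the
#' within-waveform latency ordering N2 < P3a < P3b per electrode, flagging
#' violations in an `order_ok` column.
#'
#' @param erp An `erp_waveform`.
#' @param specs List of [component_spec()]s (default the standard set for
#'   the waveform's trigger).
#' @return Long data.frame of peak observations.
#' @export
detect_components <- function(erp, specs = NULL) {
  if (is.null(specs)) specs <- default_component_specs(erp$trigger)
  rows <- list()
  for (sp in specs) {
    for (el in intersect(sp$electrodes, rownames(erp$mean))) {
      rows[[length(rows) + 1L]] <- detect_peak(erp, sp, el)
    }
  }
  obs <- do.call(rbind, rows)
  obs$order_ok <- TRUE
  for (el in unique(obs$electrode)) {
    sel <- obs$electrode == el
    lat <- function(cmp) {
      v <- obs$latency_ms[sel & obs$component == cmp]
      if (length(v)) v[1] else NA_real_
    }
    ok <- TRUE
    if (!is.na(lat("N2")) && !is.na(lat("P3a"))) ok <- ok && lat("N2") < lat("P3a")
    if (!is.na(lat("P3a")) && !is.na(lat("P3b"))) ok <- ok && lat("P3a") < lat("P3b")
    obs$order_ok[sel] <- ok
  }
  obs
}

#' Pool peak observations into an ROI latency table
#'
#' ROI pooling concatenates the per-electrode observations of the ROI's
#' sites (frontocentral = Fz, FCz, Cz; centroparietal = CPz, Pz, POz) —
#' it does not average waveforms — and summarises each
#' (group, condition, trigger, component) cell by the median and
#' mean +/- SEM of the pooled latencies.
#'
#' @param peaks Long data.frame of peak observations
#'   (from [detect_components()], possibly row-bound over participants).
#' @param roi `"frontocentral"` or `"centroparietal"`.
#' @return List with `observations` (pooled long table, `roi` column added)
#'   and `summary` (one row per cell: `n`, `median_ms`, `mean_ms`, `sem_ms`).
#' @export
pooled_latency_table <- function(peaks,
                                 roi = c("frontocentral", "centroparietal")) {
  roi <- match.arg(roi)
  els <- roi_electrodes(roi)
  obs <- peaks[peaks$electrode %in% els, , drop = FALSE]
  obs$roi <- roi
  if (nrow(obs) == 0L) stop("no observations on ", roi, " electrodes")
  key <- interaction(obs$group, obs$condition, obs$trigger, obs$component,
                     drop = TRUE)
  summ <- do.call(rbind, lapply(split(obs, key), function(d) {
    data.frame(
      group = d$group[1], condition = d$condition[1], trigger = d$trigger[1],
      component = d$component[1], roi = roi, n = nrow(d),
      median_ms = stats::median(d$latency_ms),
      mean_ms = mean(d$latency_ms),
      sem_ms = stats::sd(d$latency_ms) / sqrt(nrow(d)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summ) <- NULL
  list(observations = obs, summary = summ)
}
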