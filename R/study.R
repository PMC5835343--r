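#' Simulate the behavioral arm of a two-group study
#'
#' One gambling-task session per participant, with per-participant random
#' streams derived from the master seed so any participant can be
#' regenerated independently.
#'
#' @param n_controls,n_adhd Group sizes (defaults 18 and 18).
#' @param params [pgt_params()].
#' @param profiles Named list `controls` / `ADHD` of [agent_profile()]s.
#' @param seed Master seed.
#' @return Combined trial-log data.frame with a `group` column.
#' @export
simulate_behavior_study <- function(n_controls = 18L, n_adhd = 18L,
                                    params = pgt_params(),
                                    profiles = default_agent_profiles(),
                                    seed = 1L) {
  logs <- list()
  for (g in c("controls", "ADHD")) {
    n_g <- if (g == "controls") n_controls else n_adhd
    for (i in seq_len(n_g)) {
      pid <- sprintf("%s_%02d", if (g == "controls") "C" else "A", i)
      tr <- simulate_session(params, profiles[[g]],
                             seed = participant_seed(seed, pid),
                             participant_id = pid)
      tr$group <- g
      logs[[pid]] <- tr
    }
  }
  do.call(rbind, c(logs, list(make.row.names = FALSE)))
}

#' Simulate the electrophysiological arm and run the ERP pipeline
#'
#' For every participant: simulate a session, synthesize epoch stacks around
#' the requested trigger(s), run the preprocessing chain
#' ([erp_from_epochs()]), and extract component peak latencies. The default
#' group sizes mirror the study's usable EEG samples (18 controls, 14 ADHD).
#'
#' @param n_controls,n_adhd Group sizes (defaults 18 and 14).
#' @param params,profiles Task parameters and agent profiles.
#' @param templates Component templates.
#' @param noise Noise model.
#' @param fs Sampling rate, Hz.
#' @param channels Electrode subset.
#' @param triggers Character vector of triggers to analyse (`"S"`, `"I"`).
#' @param seed Master seed.
#' @param filter_stage Where the band-pass is applied (see
#'   [erp_from_epochs()]); `"average"` is the fast, linearly equivalent path.
#' @param specs Component specs per trigger (default standard sets).
#' @return List with `erps` (per participant, per trigger, `HF`/`LF`
#'   waveforms), `latencies` (long observation table), `logs`
#'   (epoch bookkeeping per participant x trigger), `groups` (named vector).
#' @export
simulate_erp_study <- function(n_controls = 18L, n_adhd = 14L,
                               params = pgt_params(),
                               profiles = default_agent_profiles(),
                               templates = default_templates(),
                               noise = noise_model(), fs = 1024,
                               channels = electrode_layout(),
                               triggers = "S", seed = 1L,
                               filter_stage = "average",
                               specs = NULL) {
  erps <- list(); obs <- list(); logs <- list(); groups <- character()
  for (g in c("controls", "ADHD")) {
    n_g <- if (g == "controls") n_controls else n_adhd
    for (i in seq_len(n_g)) {
      pid <- sprintf("%s_%02d", if (g == "controls") "C" else "A", i)
      pseed <- participant_seed(seed, pid)
      trials <- simulate_session(params, profiles[[g]], seed = pseed,
                                 participant_id = pid)
      erps[[pid]] <- list()
      groups[pid] <- g
      for (trg in triggers) {
        ep <- synthesize_epochs(trials, g, templates, noise, fs, channels,
                                trigger = trg,
                                seed = participant_seed(pseed, trg))
        w <- erp_from_epochs(ep, participant = pid, group = g,
                             filter_stage = filter_stage)
        erps[[pid]][[trg]] <- w
        logs[[paste(pid, trg, sep = ".")]] <- attr(w, "log")
        sp <- if (is.null(specs)) default_component_specs(trg) else specs[[trg]]
        obs[[paste(pid, trg, sep = ".")]] <-
          rbind(detect_components(w$HF, sp), detect_components(w$LF, sp))
      }
    }
  }
  list(erps = erps,
       latencies = do.call(rbind, c(obs, list(make.row.names = FALSE))),
       logs = logs, groups = groups)
}

#' Per-participant difference waves of an ERP study
#'
#' @param study Output of [simulate_erp_study()].
#' @param trigger Trigger to use.
#' @return Named list `controls` / `ADHD` of `difference_wave` lists.
#' @export
study_difference_waves <- function(study, trigger = "S") {
  out <- list(controls = list(), ADHD = list())
  for (pid in names(study$erps)) {
    w <- study$erps[[pid]][[trigger]]
    if (is.null(w)) next
    g <- study$groups[[pid]]
    out[[g]][[pid]] <- difference_wave(w$HF, w$LF)
  }
  out
}

#' Group/condition latency contrasts in the layout of a latency table
#'
#' For every (trigger, component, ROI): between-group Mann-Whitney tests on
#' the pooled latency observations within each condition, and within-group
#' Wilcoxon signed-rank tests of HF vs LF paired by (participant,
#' electrode).
#'
#' @param peaks Long peak-observation table (from [simulate_erp_study()]).
#' @return Data.frame of contrasts with U/Z statistics, p-values and effect
#'   sizes r.
#' @export
latency_contrasts <- function(peaks) {
  rows <- list()
  for (trg in unique(peaks$trigger)) {
    for (cmp in unique(peaks$component)) {
      for (roi in c("frontocentral", "centroparietal")) {
        d <- peaks[peaks$trigger == trg & peaks$component == cmp &
                     peaks$electrode %in% roi_electrodes(roi), , drop = FALSE]
        if (nrow(d) == 0L) next
        for (cond in c("HF", "LF")) {
          dc <- d[d$condition == cond, , drop = FALSE]
          a <- dc$latency_ms[dc$group == "controls"]
          b <- dc$latency_ms[dc$group == "ADHD"]
          if (length(a) && length(b)) {
            mw <- mann_whitney(a, b)
            rows[[length(rows) + 1L]] <- data.frame(
              trigger = trg, component = cmp, roi = roi,
              contrast = paste0("between_groups_", cond),
              statistic = mw$U, Z = mw$Z, p_value = mw$p_value, r = mw$r,
              stringsAsFactors = FALSE)
          }
        }
        for (grp in c("controls", "ADHD")) {
          dg <- d[d$group == grp, , drop = FALSE]
          key <- paste(dg$participant, dg$electrode)
          hf <- dg$latency_ms[dg$condition == "HF"][order(key[dg$condition == "HF"])]
          lf <- dg$latency_ms[dg$condition == "LF"][order(key[dg$condition == "LF"])]
          if (length(hf) && length(hf) == length(lf) && any(hf != lf)) {
            ws <- wilcoxon_signed(hf - lf)
            rows[[length(rows) + 1L]] <- data.frame(
              trigger = trg, component = cmp, roi = roi,
              contrast = paste0("within_", grp, "_HF_vs_LF"),
              statistic = ws$W, Z = ws$Z, p_value = ws$p_value, r = ws$r,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Write the report bundle of a full synthetic run
#'
#' Emits tidy CSVs (behavioral summaries, latency observations and pooled
#' ROI summaries, latency contrasts, per-window differential statistics) and
#' a JSON manifest recording configuration, seed, package version and the
#' per-participant epoch bookkeeping.
#'
#' @param behavior Combined trial log (from [simulate_behavior_study()]).
#' @param study ERP study (from [simulate_erp_study()]); optional.
#' @param dir Output directory.
#' @param seed Master seed used for the run (recorded in the manifest).
#' @param window_stats Optional precomputed window-statistic table.
#' @return Invisibly, the named list of files written.
#' @export
build_reports <- function(behavior, study = NULL, dir, seed = NA,
                          window_stats = NULL) {
  if (is.null(behavior) && is.null(study)) {
    stop("missing upstream outputs: need at least a behavior log or a study")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files[[name]] <<- p
  }
  manifest <- list(package = "gamblerp",
                   version = as.character(utils::packageVersion("gamblerp")),
                   seed = seed)
  if (!is.null(behavior)) {
    wr(behavior_summary_table(behavior), "behavior_summary.csv")
    manifest$n_participants_behavior <- length(unique(behavior$participant_id))
  }
  if (!is.null(study)) {
    wr(study$latencies, "latency_observations.csv")
    for (roi in c("frontocentral", "centroparietal")) {
      wr(pooled_latency_table(study$latencies, roi)$summary,
         sprintf("latency_summary_%s.csv", roi))
    }
    wr(latency_contrasts(study$latencies), "latency_contrasts.csv")
    logs <- study$logs
    manifest$epochs <- lapply(logs, function(l) l[c("n_raw", "n_retained")])
    by_pid <- split(vapply(logs, function(l) l$n_raw, numeric(1)),
                    vapply(strsplit(names(logs), ".", fixed = TRUE),
                           `[[`, "", 1L))
    manifest$raw_epochs_per_participant <-
      as.list(vapply(by_pid, sum, numeric(1)))
  }
  if (!is.null(window_stats)) wr(window_stats, "window_stats.csv")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  files[["manifest.json"]] <- file.path(dir, "manifest.json")
  invisible(files)
}
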