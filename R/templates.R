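#' Midline electrode layout and ROIs
#'
#' @return Character vector of the six midline sites (posterior to frontal).
#' @export
electrode_layout <- function() ELECTRODES

#' @rdname electrode_layout
#' @param roi `"frontocentral"` (Fz, FCz, Cz) or `"centroparietal"`
#'   (CPz, Pz, POz).
#' @export
roi_electrodes <- function(roi = c("frontocentral", "centroparietal")) {
  roi <- match.arg(roi)
  if (roi == "frontocentral") ROI_FRONTOCENTRAL else ROI_CENTROPARIETAL
}

#' An ERP component template
#'
#' A Gaussian-windowed voltage bump planted time-locked to one of the two
#' trial events (`S` = trial onset, `I` = gambling choice). `width_ms` is the
#' full width at half maximum of the bump; per-trial latency jitter is
#' Gaussian with SD `jitter_sd_ms`. Amplitude is a per-electrode magnitude in
#' microvolts; the signed peak is `polarity * amplitude`. Latency may vary by
#' group, condition and electrode; `condition_gain` optionally scales the
#' amplitude per (group, condition), which is how group-by-condition
#' interactions are planted.
#'
#' @param name Component name (e.g. `"N2"`, `"P3a"`).
#' @param trigger `"S"` or `"I"`.
#' @param polarity `+1` or `-1`.
#' @param width_ms FWHM of the Gaussian kernel, ms.
#' @param amplitude_uV Named numeric vector over electrodes (magnitudes), or
#'   a scalar applied to all six sites.
#' @param latency_ms Either a scalar (ms, same everywhere), or a nested list
#'   `latency_ms[[group]][[condition]]` whose elements are scalars or named
#'   per-electrode vectors.
#' @param jitter_sd_ms Trial-to-trial latency jitter SD, ms (default 10).
#' @param condition_gain Optional nested list `[[group]][[condition]]` of
#'   amplitude multipliers (default 1).
#' @return Object of class `component_template`.
#' @export
component_template <- function(name, trigger = c("S", "I"), polarity,
                               width_ms, amplitude_uV, latency_ms,
                               jitter_sd_ms = 10,
                               condition_gain = NULL) {
  trigger <- match.arg(trigger)
  stopifnot(polarity %in% c(-1, 1), width_ms > 0, jitter_sd_ms >= 0)
  if (length(amplitude_uV) == 1L && is.null(names(amplitude_uV))) {
    amplitude_uV <- stats::setNames(rep(amplitude_uV, length(ELECTRODES)),
                                    ELECTRODES)
  }
  stopifnot(all(amplitude_uV >= 0))
  structure(
    list(name = name, trigger = trigger, polarity = polarity,
         width_ms = width_ms, amplitude_uV = amplitude_uV,
         latency_ms = latency_ms, jitter_sd_ms = jitter_sd_ms,
         condition_gain = condition_gain),
    class = "component_template"
  )
}

#' Look up a template's mean latency / gain for one cell
#'
#' @param template A [component_template()].
#' @param group,condition,electrode Cell selectors.
#' @return Latency in ms (or amplitude gain).
#' @export
template_latency <- function(template, group, condition, electrode) {
  lat <- template$latency_ms
  if (is.numeric(lat)) {
    return(if (length(lat) == 1L) lat else unname(lat[[electrode]]))
  }
  v <- lat[[group]][[condition]]
  if (length(v) == 1L && is.null(names(v))) return(v)
  unname(v[[electrode]])
}

#' @rdname template_latency
#' @export
template_gain <- function(template, group, condition) {
  cg <- template$condition_gain
  if (is.null(cg)) return(1)
  g <- cg[[group]][[condition]]
  if (is.null(g)) 1 else g
}

# Latency grid keyed by ROI: values are the study-calibrated medians (ms).
# fc = frontocentral (Fz, FCz, Cz); cp = centroparietal (CPz, Pz, POz).
roi_latency <- function(fc, cp) {
  stats::setNames(c(cp, cp, cp, fc, fc, fc), ELECTRODES)
}

lat_by_cell <- function(c_hf_fc, c_hf_cp, a_hf_fc, a_hf_cp,
                        c_lf_fc, c_lf_cp, a_lf_fc, a_lf_cp) {
  list(
    controls = list(HF = roi_latency(c_hf_fc, c_hf_cp),
                    LF = roi_latency(c_lf_fc, c_lf_cp)),
    ADHD = list(HF = roi_latency(a_hf_fc, a_hf_cp),
                LF = roi_latency(a_lf_fc, a_lf_cp))
  )
}

# linear amplitude taper across the 6 midline sites (posterior -> frontal)
amp_taper <- function(post, front) {
  stats::setNames(seq(post, front, length.out = length(ELECTRODES)), ELECTRODES)
}

#' Default component template set
#'
#' Templates for the eight waves the generator plants, with latencies
#' calibrated to the study's group/condition medians where those were
#' reported (trial-onset and post-choice N2, P3a, P3b per ROI) and to the
#' approximate latencies stated for the remaining components (C1 ~70 ms;
#' N500 ~490 ms after trial onset; N400-like ~490 ms and LPP ~850 ms after
#' the choice; premotor build-up ~150 ms before the choice). Amplitudes are
#' free parameters of the generator (none were reported); defaults are
#' conventional magnitudes with a linear posterior-frontal taper matching
#' each wave's described topography.
#'
#' @param jitter_sd_ms Trial-to-trial latency jitter SD (default 10 ms).
#' @return List of [component_template()] objects.
#' @export
default_templates <- function(jitter_sd_ms = 10) {
  list(
    component_template("C1", "S", +1, width_ms = 30,
      amplitude_uV = c(POz = 3, Pz = 2.5, CPz = 0.8, Cz = 0.2, FCz = 0, Fz = 0),
      latency_ms = 70, jitter_sd_ms = jitter_sd_ms / 2),
    component_template("N2", "S", -1, width_ms = 40,
      amplitude_uV = amp_taper(3, 5),
      latency_ms = lat_by_cell(164.0, 190.5, 173.5, 179.0,
                               171.0, 189.5, 174.0, 187.0),
      jitter_sd_ms = jitter_sd_ms),
    component_template("P3a", "S", +1, width_ms = 60,
      amplitude_uV = amp_taper(5, 8),
      latency_ms = lat_by_cell(246.5, 251.0, 243.0, 255.5,
                               262.0, 264.0, 247.0, 260.0),
      jitter_sd_ms = jitter_sd_ms),
    component_template("P3b", "S", +1, width_ms = 80,
      amplitude_uV = amp_taper(10, 7),
      latency_ms = lat_by_cell(351.0, 353.0, 349.0, 348.0,
                               356.0, 357.0, 363.5, 354.0),
      jitter_sd_ms = jitter_sd_ms),
    component_template("N500", "S", -1, width_ms = 150,
      amplitude_uV = amp_taper(1, 4),
      latency_ms = 490, jitter_sd_ms = jitter_sd_ms,
      condition_gain = list(controls = list(HF = 1, LF = 1),
                            ADHD = list(HF = 1.4, LF = 0.8))),
    component_template("N2", "I", -1, width_ms = 40,
      amplitude_uV = amp_taper(3, 5),
      latency_ms = lat_by_cell(167.5, 178.5, 174.0, 181.0,
                               165.0, 178.0, 174.5, 184.0),
      jitter_sd_ms = jitter_sd_ms),
    component_template("P3a", "I", +1, width_ms = 60,
      amplitude_uV = amp_taper(5, 8),
      latency_ms = lat_by_cell(235.0, 244.0, 242.0, 245.0,
                               237.5, 239.5, 245.0, 251.5),
      jitter_sd_ms = jitter_sd_ms),
    component_template("P3b", "I", +1, width_ms = 80,
      amplitude_uV = amp_taper(10, 7),
      latency_ms = lat_by_cell(351.0, 360.0, 342.0, 350.5,
                               360.0, 370.5, 350.5, 362.0),
      jitter_sd_ms = jitter_sd_ms),
    component_template("N400_like", "I", -1, width_ms = 150,
      amplitude_uV = c(POz = 1.5, Pz = 2.5, CPz = 3.5, Cz = 5, FCz = 4, Fz = 3),
      latency_ms = 490, jitter_sd_ms = jitter_sd_ms,
      condition_gain = list(controls = list(HF = 1, LF = 1),
                            ADHD = list(HF = 0.8, LF = 1.3))),
    component_template("LPP", "I", +1, width_ms = 180,
      amplitude_uV = amp_taper(4, 2),
      latency_ms = 850, jitter_sd_ms = jitter_sd_ms),
    component_template("M", "I", -1, width_ms = 100,
      amplitude_uV = c(POz = 1, Pz = 2, CPz = 2, Cz = 2, FCz = 1.5, Fz = 1),
      latency_ms = -150, jitter_sd_ms = jitter_sd_ms)
  )
}

#' Add a frontal group-by-condition amplitude interaction
#'
#' Returns a template set in which one component acquires opposite-signed
#' HF-vs-LF amplitude modulation in the two groups (controls larger in LF,
#' ADHD larger in HF), with a frontally tapered amplitude so the effect is
#' maximal at Fz and absent posteriorly. Used to exercise the differential
#' waveform analysis.
#'
#' @param templates Template list to modify (default [default_templates()]).
#' @param component Name (+ trigger) of the component to modulate.
#' @param trigger Trigger of the component to modulate.
#' @param gain Interaction strength: gains are `1 +/- gain`. The default is
#'   large enough that the band-separation test detects the effect reliably
#'   at 14 participants per group.
#' @return Modified template list.
#' @export
templates_with_frontal_interaction <- function(templates = default_templates(),
                                               component = "N2", trigger = "S",
                                               gain = 0.8) {
  for (i in seq_along(templates)) {
    tp <- templates[[i]]
    if (tp$name == component && tp$trigger == trigger) {
      tp$amplitude_uV <- c(POz = 0, Pz = 0.3, CPz = 1, Cz = 2.5,
                           FCz = 4, Fz = 5)
      tp$condition_gain <- list(
        controls = list(HF = 1 - gain, LF = 1 + gain),
        ADHD = list(HF = 1 + gain, LF = 1 - gain)
      )
      templates[[i]] <- tp
    }
  }
  templates
}

#' Render one component kernel on a time grid
#'
#' Evaluates the Gaussian bump of a template for a given (group, condition,
#' electrode) cell, with an optional latency jitter draw. With zero jitter
#' the kernel extremum sits exactly at the template's mean latency.
#'
#' @param template A [component_template()].
#' @param group,condition,electrode Cell selectors.
#' @param t_ms Time grid in ms (relative to the template's trigger).
#' @param jitter_ms Latency jitter to apply, in ms. Use
#'   `rnorm(1, 0, template$jitter_sd_ms)` for a stochastic render; default 0.
#' @return Numeric vector of microvolts over `t_ms`.
#' @export
render_component <- function(template, group, condition, electrode, t_ms,
                             jitter_ms = 0) {
  stopifnot(electrode %in% names(template$amplitude_uV))
  lat <- template_latency(template, group, condition, electrode) + jitter_ms
  amp <- template$amplitude_uV[[electrode]] *
    template_gain(template, group, condition) * template$polarity
  if (amp == 0) return(numeric(length(t_ms)))
  sigma <- template$width_ms / (2 * sqrt(2 * log(2)))  # FWHM -> SD
  amp * exp(-((t_ms - lat)^2) / (2 * sigma^2))
}
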