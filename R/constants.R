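# Electrode layout used throughout: midline sites, posterior -> frontal.
ELECTRODES <- c("POz", "Pz", "CPz", "Cz", "FCz", "Fz")
ROI_FRONTOCENTRAL <- c("Fz", "FCz", "Cz")
ROI_CENTROPARIETAL <- c("CPz", "Pz", "POz")

# artifact/oscillation topographies (posterior -> frontal)
BLINK_WEIGHTS <- stats::setNames(c(0.15, 0.25, 0.4, 0.6, 0.8, 1), ELECTRODES)
ALPHA_WEIGHTS <- stats::setNames(c(1, 0.9, 0.7, 0.5, 0.4, 0.3), ELECTRODES)
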