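Package: gamblerp
Title: Simulation and ERP Analysis of a Probabilistic Gambling Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate a Gneezy-Potters style probabilistic gambling
    task with high- and low-frequency outcome feedback, to synthesize
    multichannel EEG containing event-locked potentials with realistic noise
    and artifacts, and to analyse both halves: behavioral endpoints (total
    gains, risk index, robustly filtered response times), an ERP
    preprocessing chain (band-pass filtering, epoching, baseline correction,
    artifact rejection, averaging), named component peak-latency extraction
    with frontocentral/centroparietal pooling, a feedback-frequency
    differential-waveform analysis with confidence-band integration,
    permutation tests and bootstrap confidence intervals, and nonparametric
    test statistics with effect sizes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
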