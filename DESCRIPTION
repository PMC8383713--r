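Package: msnascore
Title: Automated Burst Detection and Probabilistic Scoring for Muscle
    Sympathetic Nerve Activity Recordings
Version: 0.1.0
Authors@R:
    person("MSNA", "Tools", email = "msnascore@example.org", role = c("aut", "cre"))
Description: Detects candidate sympathetic bursts in integrated
    microneurography (MSNA) recordings sampled at 1 kHz and scores every
    candidate with three independent lines of evidence: a dense
    neural-network shape classifier, a cardiac-cycle timing likelihood
    anchored on ECG R-waves and the diastolic blood-pressure nadir, and a
    spectral signal-quality index based on the median magnitude of the
    discrete Fourier transform of the surrounding minute of signal. The
    evidence is combined into a single 0-1 composite validity score via a
    weighted circular profile. Includes a seeded physiological simulator
    (ECG, continuous blood pressure, integrated MSNA with ground-truth
    burst times) so the full pipeline is testable without human data, a
    training harness for the classifiers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
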