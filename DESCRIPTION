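Package: crmaneuver
Title: Cardiorespiratory Indices from a Paced-Breathing Maneuver
Version: 0.1.0
Authors@R:
    person("Oleh", "Maren", email = "oleh.maren@posteo.net", role = c("aut", "cre"))
Description: Analysis pipeline for combined heart-beat, beat-to-beat blood
    pressure and respiratory airflow recordings acquired during a three-epoch
    breathing maneuver (spontaneous breathing, paced breathing at 6 and at 15
    breaths per minute, 2 min each). Computes breathing-pattern indices,
    band-power spectra of RR intervals, systolic/diastolic pressure and the
    breath-wise ventilation series, the spectral baroreflex alpha coefficient,
    Baevsky geometric heart-rhythm indices, derived systemic hemodynamics,
    cardiorespiratory synchronization indices, per-epoch increments and their
    classification against shipped reference quartile limits, plus cohort
    statistics with an exact Wilcoxon signed-rank test. Includes a synthetic
    cohort generator based on integral pulse frequency modulation with
    respiratory and baroreflex coupling, so the whole pipeline is testable
    against known ground truth without recording hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
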