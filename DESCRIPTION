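Package: wakeslow
Title: Wake Slow Waves, Interictal Discharges, and Their Prognostic Interplay in Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detection of interictal epileptiform discharges (IEDs) and local
    wake slow waves (LoWS) in multichannel intracranial EEG, and analysis of
    their temporal interplay. Provides a Hilbert-envelope IED detector with
    burst collapsing, a half-wave LoWS detector with an amplitude percentile
    filter and a high-gamma downstate gate, event-locked high-gamma
    excitability estimates, incidence-corrected inter-event delay statistics,
    linear mixed-effects outcome models, repeated-measures preictal rate
    analyses, and a patient-level classifier of surgical outcome from the
    resected/non-resected corrected IED-to-LoWS delay ratio. Includes a
    synthetic iEEG generator with ground-truth event logs and simulated
    surgical cohorts so that every stage is testable without clinical data,
    plus EDF and BIDS-style TSV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
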