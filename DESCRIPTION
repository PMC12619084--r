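Package: srseize
Title: Seizure Detection, Burden Metrics and Resampling Statistics for
    Hippocampal LFP Recordings, with TRAP Enrichment Filters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects spontaneous recurrent seizures in single-channel
    hippocampal local field potential (LFP) recordings by amplitude
    thresholding of the high-pass filtered signal (3x baseline SD, >10 s),
    computes seizure-burden metrics (frequency, duration, cumulative
    duration), and provides the accompanying statistics: a pooled
    bootstrap-resampling test for differences in means, a two-sample
    Kolmogorov-Smirnov comparison, and an extra sum-of-squares F test for
    nested stimulus-response curve fits. Also implements the TRAP/RiboTag
    astrocyte-enrichment differential-expression filter chain (FPKM,
    fold-change and adjusted-p thresholds, IP/input enrichment, top-k
    ranking) and seeded synthetic-data generators (LFP with ground-truth
    events, grouped metrics, FPKM tables with planted truth) so that the
    whole pipeline is testable without external recordings. Reads and
    writes EDF and a raw float32 fixture format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
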