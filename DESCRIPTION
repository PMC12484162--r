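Package: laborHRV
Title: Maternal Heart Rate Variability and Time to Delivery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of maternal heart rate variability (HRV) in
    relation to the timing of labor. Extracts maternal R peaks from
    electrohysterogram (EHG) or abdominal ECG recordings (zero-phase high-pass
    filtering, amplitude normalization, threshold peak detection with a
    refractory period, 5-minute segment selection), conditions the resulting
    RR-interval series (automated ectopic-beat flagging and duration-preserving
    run-mean correction), computes short-term time-domain (mean RR, SDNN,
    RMSSD) and frequency-domain (VLF, LF, HF band powers, LF/HF ratio) HRV
    indices, and applies cohort statistics: exclusion filters, time to
    delivery, a Monte-Carlo Lilliefors normality gate, and Spearman
    correlations with confidence intervals. A fully seeded synthetic-data
    module (integral pulse frequency modulation tachograms, Gaussian-QRS ECG,
    EHG with uterine contraction bursts, cohorts with planted HRV-outcome
    correlations) makes every stage testable without clinical recordings.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nortest,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
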