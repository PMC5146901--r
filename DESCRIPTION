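Package: rhythmoscope
Title: Daily Rhythmicity Analysis of qPCR Gene Expression Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterising daily (24-hour) rhythms in
    quantitative PCR gene expression time courses, as used in studies of
    circadian clock gene transcription in fish skeletal muscle. Implements
    relative quantification by the 2^-ddCt method with geNorm reference-gene
    stability ranking, single-cosinor rhythmometry with the amplitude
    noise/signal statistic SE(A)/A and a P < 0.3 rhythmicity rule, per-timepoint
    one-way ANOVA with Duncan's multiple-range letter groupings, and
    rhythm-gated Pearson correlation screening between gene pairs. A seeded
    synthetic-data generator emulates the nine-Zeitgeber-time, six-replicate
    sampling design so the whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
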