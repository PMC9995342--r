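Package: episial
Title: Targeted Detection of Sialylated Erythropoietin Glycopeptides in LC-HRMS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted analysis of tetra-sialylated N-glycopeptides of
    recombinant erythropoietin (rEPO) by liquid chromatography coupled to
    high-resolution mass spectrometry. Provides in-silico multi-enzyme
    digestion with missed cleavages, N-glycosylation sequon discovery,
    monoisotopic mass and m/z arithmetic for glycopeptides, diagnostic
    oxonium / backbone / Y-ladder fragment generation, transition
    (inclusion) list assembly, targeted detection in centroided runs
    (XIC extraction, robust signal-to-noise estimation, MS2 product-ion
    confirmation), a bioanalytical validation battery (linearity,
    carryover, intraday precision, selectivity, matrix effect, limit of
    detection), and a synthetic-run generator with known ground truth so
    the whole pipeline can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    mzR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
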