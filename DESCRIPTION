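Package: icgaFlap
Title: Skin-Flap Perfusion Mapping and Necrosis Risk Assessment from
    Indocyanine Green Angiography
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of intraoperative indocyanine green
    angiography (ICG-A) recordings of mastectomy skin flaps. Detects the
    plateau phase of the fluorescence bolus from the time-intensity curve,
    extracts a plateau-phase perfusion map, normalizes it to relative
    perfusion units (RPU, brightest in-flap point = 100), segments the
    hypoperfused region (RPU below a 30 percent cutoff, nipple excluded),
    and computes the hypoperfused-area percent ratio together with the
    15 percent reconstruction-decision rule and the one-third eligibility
    screen. Also provides cohort-level diagnostic statistics (confusion
    tables, sensitivity/specificity/PPV/NPV with exact Clopper-Pearson
    intervals, two-sided Fisher exact tests, summary-statistic t tests)
    and a synthetic ICG-A generator with perforator-territory structure
    and known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tiff, png, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
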