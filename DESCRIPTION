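Package: tracerscreen
Title: Rule-Based Screening of LC-HRMS Data for Tracer-Derived Isotopolog Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated screening of centroided LC-HRMS full-scan chromatograms for
    user-definable isotopolog patterns, such as those produced by iterative
    incorporation of 13C2-labelled (or, in a globally 13C-labelled background,
    native 12C2) malonate-derived extension units into fatty acids and
    polyketides. Candidate signals are verified at the MS-scan level against a
    declarative rule set (presence, absence, intensity and ratio rules), grouped
    by time-aware hierarchical clustering, re-verified in the chromatographic
    domain with continuous-wavelet-transform peak picking, Pearson coelution
    testing and peak-area ratio checks, bracketed across samples, convoluted
    into metabolite-level groups, reintegrated and reported as a tab-separated
    data matrix. A ground-truthed synthetic-run generator with an isotopolog
    incorporation model supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mzR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
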