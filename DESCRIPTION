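Package: jointGBLUP
Title: Cross-Population Genomic Prediction with Joint Reference Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying multi-population genomic selection in dairy
    cattle: a forward-in-time simulator of two Holstein-like populations with
    drift-generated linkage disequilibrium (LD), half-sib family structure and
    deregressed-proof (DRP) phenotypes; LD measures and the cross-population
    LD-consistency statistic; genomic relationship matrices (VanRaden method 1);
    single-trait and two-trait across-population GBLUP with AI-REML variance
    component estimation; validation designs (relationship-filtered bull test
    sets, half-sib-family cross-validation) with genetic-trend correction; and
    the deterministic expected reliability of genomic prediction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
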