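Package: gsrpipe
Title: Glucose-Specific Responsive Gene Analysis for Reciprocal
    Medium-Shift Transcriptome and Metabolome Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies glucose-specific responsive (GSR) genes from a
    reciprocal medium-shift RNA-seq design (low/high glucose steady
    states plus both shift directions), using a conditional
    negative-binomial exact test, Benjamini-Hochberg FDR control, and a
    monotonicity classification of the response with respect to glucose
    level. Provides binomial pathway enrichment with log2
    fold-enrichment, a pathway direction-consistency statistic based on
    a Binomial(N, 2^-M) upper tail, LC-MS metabolite table QC
    (relative-standard-deviation filtering, median normalization, ppm
    mass matching) and differential-compound calling, and integration of
    summative enzyme-level transcript calls with metabolite calls over
    hard-coded glucose-assimilation pathway graphs (EMP, ED, OPP, starch
    biosynthesis) to infer the preferred glucose-oxidation route.
    Includes a negative-binomial simulator with planted ground truth for
    end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
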