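Package: chromrsm
Title: Chromatographic Method Optimization with Box-Behnken Designs and
    Desirability Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and validating gradient-elution HPLC
    separation methods by designed experiments. Builds three-level
    Box-Behnken designs with center replicates, computes chromatographic
    responses (pairwise peak resolution and analysis time) from peak
    lists, fits full second-order response-surface polynomials on coded
    factors with per-term significance testing, and locates optimal
    separation conditions by Derringer-style importance-weighted
    desirability optimization. Includes a phenomenological
    gradient-elution simulator (linear-solvent-strength retention with
    Henderson-Hasselbalch pH dependence and plate-count peak widths) for
    end-to-end pipeline testing with known ground truth, ICH Q2(R1)-style
    method-validation metrics (calibration linearity, detection and
    quantification limits, recovery, precision), and regulatory
    concentration-limit compliance checks for common food additives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
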