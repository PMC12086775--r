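Package: cmcpmod
Title: Closed MCP-Mod Contrast Tests for Dose-Control Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Confirmatory dose-response testing with model-based multiple
    contrast tests embedded in a closed testing procedure. Provides optimal
    and nonnegativity-constrained contrast coefficients for candidate
    dose-response shapes (Emax, sigmoid Emax, beta, exponential, linear),
    multivariate-t multiplicity adjustment, the closed MCP-Mod test yielding
    familywise-error-controlled p-values for each dose versus placebo,
    reference procedures (single-step and step-down Dunnett, Hochberg,
    Bonferroni, fixed sequence), a trial simulator for operating
    characteristics, and a graphical extension for testing a primary and a
    secondary endpoint.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    mvtnorm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
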