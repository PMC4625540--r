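Package: signcon
Title: Sign Consistency Analysis of Interaction Graphs and Perturbation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Confronts signed directed interaction graphs (gene regulatory or
    signaling networks) with discretized steady-state shift experimental
    profiles. Implements four sign-consistency notions (weak and strong
    propagation, with and without foundedness filtering of positive feedback
    loops), enumeration of admissible total labelings, cautious prediction of
    unmeasured node behaviors with strong and weak predictions, repair of
    inconsistent instances by minimal correction sets and scenario fitting,
    and evaluation machinery (inconsistency index, recovery rate, information
    gain, precision, confusion matrices, cross-validation and shuffle-null
    procedures). Includes a synthetic instance generator with a known hidden
    labeling for end-to-end validation, strict plain-text file formats and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
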