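Package: rnaitrigger
Title: Design of Long Double-Stranded RNAi Triggers and Off-Target Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs long double-stranded RNA (dsRNA) triggers for RNA
    interference and predicts their off-targets. Enumerates all candidate
    small interfering RNAs (siRNAs) from a trigger, matches them against a
    transcript database with an exact k-mer index (0-2 mismatches via
    seed-and-verify), scores guide-strand selection with terminal-nucleotide
    and nearest-neighbor end-stability rules, computes local target-site
    accessibility with a windowed McCaskill partition function under a
    reduced stacking energy model, and classifies siRNAs under a
    high-sensitivity (off-target search) and a high-efficiency (construct
    design) rule set. Includes generators for molecular-clock and
    window-construct validation sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    ggplot2,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
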