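Package: isofinder
Title: Untargeted Stable-Isotope Tracing of Metabolite and Lipid Isotopomers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds and quantifies 13C mass isotopomers of identified metabolites
    and lipids in untargeted LC-MS data. An identification list from unlabeled
    samples (metabolite and lipid export dialects) is pooled into a reference,
    expanded to theoretical isotopomer m/z ladders, and matched against MS1
    feature lists of labeled samples with a joint m/z-retention-time score that
    screens false positives such as co-eluting isotopologue envelopes of heavier
    lipids. Includes MS1 peak picking from centroided mzML/mzXML, labeling-ratio
    and isotopomer-distribution summaries with lipid class and fatty-acid-chain
    aggregation, a ground-truth simulator with decoys and co-eluting interferers
    for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
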