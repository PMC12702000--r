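Package: allonet
Title: Allosteric Network Mapping from Difference Density and Local HDX-MS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Dual-modality mapping of mutation-driven allosteric networks in a
    protein. Computes weighted isomorphous difference electron-density maps
    (Fmut - FWT) from merged structure-factor amplitudes, scores them per
    residue by integrating absolute difference density above a noise threshold
    (IADDAT), transforms peptide-level hydrogen-deuterium exchange mass
    spectrometry (HDX-MS) centroid masses into back-exchange-corrected
    percent-deuteration differences projected to residue level, and combines
    the thresholded tracks into a residue network whose overlap with
    externally supplied residue sectors is quantified by Jaccard ratios and
    hypergeometric tests. Includes a fully synthetic data generator (toy
    crystal, simulated reflections, pepsin-like peptide maps) with known
    ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
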