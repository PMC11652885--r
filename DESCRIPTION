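Package: orcoscreen
Title: Two-Step Virtual Screening for Mosquito ORco Orthosteric Antagonists
Version: 0.1.0
Authors@R: person("ORco Screening", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ligand-based discovery toolkit for antagonists of the insect
    odorant receptor coreceptor (ORco) channel. Implements a four-feature
    pharmacophore screen (two centroid hydrophobic features, one atom-centred
    hydrophobic feature and one projected hydrogen-bond donor location) with
    distance-geometry conformer matching, a two-descriptor (KierA2,
    SlogP_VSA1) RBF-kernel support vector machine filter, virtual-screening
    evaluation statistics (sensitivity, specificity, power metric),
    competition dose-response analytics (four-parameter logistic IC50
    fitting, orthosteric versus allosteric mechanism calls) and repellency
    indices. Ships the transcribed reference tables of a published
    mosquito-volatile screening campaign as plain-text fixtures, plus seeded
    synthetic generators for dose-response curves and feature-point
    geometries. Molecular parsing, 3D embedding and Crippen atomic
    parameters are obtained from the system RDKit installation through a
    small Python bridge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on PATH
Config/testthat/edition: 3
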