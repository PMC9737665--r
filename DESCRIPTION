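Package: decarbID
Title: Substrate and Product Identification for Amino Acid Decarboxylases
    from LC-MS Enzyme Assays
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies substrates and products of amino acid decarboxylases
    from in vitro enzyme-reaction LC-MS experiments. Implements an untargeted
    workflow (centroid mass detection, intensity-seeded extracted-ion
    chromatogram building, Savitzky-Golay smoothing, local-minimum peak
    resolution, join alignment with gap filling and duplicate filtering),
    ranks metabolites by the vector-control/enzyme signal ratio, pairs
    depleted substrates with accumulated products via the CO2 neutral-loss
    mass shift (43.98983 Da), and confirms identities by retention time,
    accurate mass and MS2 cosine matching. A targeted companion quantifies an
    amino acid MRM transition panel. A seeded simulator generates
    vector-versus-enzyme experiments (complex metabolite backgrounds,
    substrate depletion, product accumulation, replicate noise) for
    calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    ProtGenerics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    mzR,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
biocViews: MassSpectrometry, Metabolomics, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
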