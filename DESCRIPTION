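Package: venomkit
Title: Secretome Abundance, Conservation and Expression Analysis for Nematode Venom Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the excreted/secreted protein (venom) repertoire of
    activated entomopathogenic nematode infective juveniles. Implements emPAI
    (exponentially modified protein abundance index) scoring from in-silico
    trypsin/Lys-C digestion and observed peptide identifications, orthology-cluster
    based conservation categorisation of venom proteins with emPAI-weighted venom
    composition, Pfam-style gene-family venom-coverage statistics at an E-value
    threshold, transcriptome-secretome integration (log transforms, quantile
    normalisation, batch-mean correction, sample correlation/PCA, differential
    expression thresholding, Venn overlaps, operon-like genomic proximity grouping,
    RNA-protein correlation), secretion dosimetry, and a fully seeded synthetic-data
    generator with planted truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    limma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
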