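Package: cyclominer
Title: Cyclotide Precursor Mining, Signature Classification and Mass-Spectral Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines cyclotide precursor coding sequences from assembled plant
    transcripts, anchors them to a consensus coordinate system, classifies them
    by prodomain indel signatures into lineages, molecular series and molecular
    species, predicts mature-peptide monoisotopic masses, and matches those
    predictions to centroided LC-MS peak lists via charge-state deconvolution
    and an alkylation-shift confirmation.  Includes a synthetic-data generator
    that produces transcriptomes, FPKM tables and peak lists with a ground-truth
    ledger for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
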