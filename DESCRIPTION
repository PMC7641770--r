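Package: hepnmnt
Title: Discovery of HEPN/MNT Toxin-Antitoxin Pairs and Adenylylation Mass Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome mining and mass-spectrometric analysis of HEPN/MNT
    toxin-antitoxin (TA) systems. Scans proteomes for the toxin signature
    motif RX4HXY and the antitoxin nucleotidyltransferase signature
    GSX10DXD, both as exact gapped patterns and as position weight
    matrices with exact p-values; pairs motif-bearing proteins encoded by
    neighboring genes; classifies pairs into Class I and Class II by Pfam
    family evidence; and summarises prevalence per taxon. A companion
    mass module computes molecular masses from elemental composition,
    identifies phosphodiesterase cleavage products such as 5'-AMP,
    deconvolutes electrospray charge ladders to neutral masses, and
    infers the number of AMP moieties from intact-protein mass shifts.
    Includes a synthetic-data generator emitting annotated genomes with
    planted TA pairs plus ground-truth manifests, and simulated ESI
    spectra, for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
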