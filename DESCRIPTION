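Package: lampyritox
Title: Proteo-Transcriptomic Annotation of Putative Neurotoxins in Firefly Larval Midgut Secretions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and annotate putative neurotoxin precursors in
    proteo-transcriptomic surveys of predatory firefly (Lampyris) larval midgut
    secretions. The pipeline finds open reading frames in transcript contigs,
    segments precursors into signal peptide, propeptide and mature peptide using
    signal-peptide annotations and basic-residue cleavage motifs (monobasic,
    dibasic and processing-quadruplet), computes theoretical monoisotopic
    [M+H]+ masses with disulfide and amidation corrections, matches them
    against MALDI-TOF peak lists with cross-spectrum reproducibility scoring,
    classifies precursors from BLAST and InterPro evidence with an
    accordance-based best-hit rule and coverage/score quality gates, and
    assigns disulfide bridges from predicted-structure sulfur distances.
    A synthetic-data generator produces complete fixture cohorts with known
    ground truth so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
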