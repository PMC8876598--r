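Package: venomtx
Title: Venom-Gland EST Annotation and Peptide Toxin Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for mining peptide toxins from venom-gland
    cDNA-library and transcriptome sequences. Provides EST quality control,
    six-frame translation and three-way functional annotation against a
    bundled reference protein set, single-linkage contig clustering with
    unique-gene and unique-protein bookkeeping, toxin precursor segmentation
    into signal peptide, propeptide (processing quadruplet motif rule) and
    mature peptide, C-terminal amidation detection, cysteine-framework
    extraction in adjacency notation with disulfide-connectivity template
    assignment, homology/framework-based family grouping, theoretical
    peptide-mass calculation with disulfide and amidation corrections, and
    matching of MALDI-TOF peak lists under singly- and doubly-protonated ion
    interpretations. A deterministic synthetic-library generator with a
    ground-truth manifest supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
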