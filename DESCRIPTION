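Package: srbkit
Title: Comparative Sequence and Structure Analysis of Class B Scavenger Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative characterization of class B scavenger
    receptors (SR-Bs) across eukaryotes: census of CD36-domain proteins by
    their TM-CD36-TM transmembrane architecture (with a built-in Kyte-Doolittle
    hydropathy predictor and parsers for HMMER domtblout and TMHMM tables),
    ectodomain extraction and length analytics with a >500 aa expansion flag,
    alignment analytics (consensus, conservation, pairwise identity,
    lineage-specific insertion columns, and disulfide-bridge cysteine homolog
    mapping with an expansion false-positive exclusion rule), position-weight
    matrix motif scanning with STREME-style sequence scores on a 0-100 scale,
    rigid-body structure superposition with iterative spatial-adjacency residue
    pairing, per-residue RMSD-calpha binning and unaligned-expansion detection,
    and grid-based cavity/pocket/tunnel detection at a configurable probe
    radius. Includes synthetic-data generators (sequences, gold alignments,
    idealized beta-barrel/helix structures, cavity test shapes) so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), knitr
Config/testthat/edition: 3
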