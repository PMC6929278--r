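Package: hexablock
Title: Local Sequence and Spatial Features for Protein-Protein Interface
    Identification and Docking Pose Re-Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies protein-protein interfaces and re-ranks rigid-body
    docking poses from local evolutionary-profile features. Per-residue
    profiles (physicochemical properties and position-specific scoring
    matrices) are summarised by multi-scale local average blocks over an
    11-residue sequence window and by hexagon blocks over six azimuthal
    spatial sectors around each residue. Per-pose feature vectors pooled
    over interface residues feed a support vector regression trained
    against interface RMSD, which orders decoy poses and selects
    consensus binding residues. Includes CAPRI-style evaluation (fraction
    of native contacts, fraction of non-native contacts, interface RMSD,
    quality classes) and deterministic synthetic-fixture generators for
    end-to-end testing without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    e1071,
    Biostrings,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
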