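Package: silmotif
Title: Tetraspanin Small Intracellular Loop Consensus and M-Motif Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the small intracellular loop (SIL) of
    tetraspanins and related four-transmembrane proteins. Extracts the
    TMS2-TMS3 linker from topology-annotated sequences, builds an anchored
    alignment around the most N-terminal acidic (or, failing that, basic)
    residue, computes per-position residue frequencies and calls consensus
    residues with the f >= f_mean + SD rule. On the structural side it
    computes backbone phi/psi dihedrals from PDB/mmCIF coordinates,
    classifies Ramachandran regions, detects the M-shaped five-residue
    inter-helix turn (alphaR, alphaL, beta, alphaR, alphaR), scores backbone
    co-planarity by least-squares plane fitting, and screens salt bridges
    and polar contacts by minimum heavy-atom distance. Includes seeded
    synthetic generators (torsion-to-Cartesian backbone builder, hairpin and
    salt-bridge fixtures, sequence families with planted cores) so the whole
    pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
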