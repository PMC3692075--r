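Package: trmsd
Title: Fine-Grained Structure-Based Classification of Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns a multiple sequence alignment of homologous proteins with
    known three-dimensional structures into a fine-grained structure-based
    clustering tree. For every ungapped alignment column an inter-structure
    distance matrix is computed from distance-RMSD (dRMSD) differences of
    intramolecular distances, each matrix is turned into a neighbor-joining
    tree, and the per-column trees are combined by strict majority-rule
    consensus; each internal node of the consensus carries the number of
    ungapped positions supporting it, and each column is scored for its
    contribution to the final topology (the blue-to-red discriminativeness
    scheme). Includes readers and writers for aligned FASTA, ClustalW, PDB,
    Newick and PHYLIP square matrices, a command-line interface, and a
    synthetic-structure generator that fabricates protein families with
    planted conformational sub-clusters for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    bio3d,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
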