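Package: zincsites
Title: Detection and Redundancy Clustering of Zinc Binding Sites in Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies biologically relevant zinc (and co-active metal)
    binding sites in PDB-format protein structures. Generates the biological
    assembly from REMARK 350 instructions, finds liganding atoms with a
    3 Angstrom distance / 45 degree angle rule, groups metals that share
    liganding residues into sites, discards adventitious zinc salts and
    symmetry duplicates, clusters equivalent sites across structures via
    90 percent sequence-identity chain clusters and binding-site
    fingerprints, and computes site-level statistics (residue signatures,
    coordination modes, liganding distance distributions, co-active metal
    tables, enzymatic enrichment). Includes a seeded synthetic-structure
    generator with constructive ground truth for validation, and an SQLite
    batch database builder with JSON/FASTA/CSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    DBI,
    RSQLite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    igraph,
    optparse
Config/testthat/edition: 3
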