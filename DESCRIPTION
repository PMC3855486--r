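Package: pncctools
Title: Molecular Classification and Enzyme Kinetics of NMN Deamidases
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the molecular classification of nicotinamide
    mononucleotide (NMN) deamidases (PncC family). Implements a degenerate
    block-consensus motif grammar and scanner, a curated catalog of
    conserved MocF, interdomain and CinA blocks with per-lineage variants
    and active-site key residues, information-content conserved-block
    detection on multiple alignments, domain-architecture and functionality
    calling with lineage assignment, affine-gap pairwise alignment,
    neighbor-joining phylogeny with bootstrap supports, Michaelis-Menten and
    Hill kinetics fitting for the coupled glutamate-dehydrogenase assay,
    ligand-efficiency arithmetic, and a seeded synthetic-data generator that
    produces labeled per-lineage sequence panels, known-truth alignments and
    noisy initial-rate datasets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
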