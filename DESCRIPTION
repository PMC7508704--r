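Package: rnasse
Title: RNA 3D Structure Assembly from Smallest-Secondary-Element Template
    Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds searchable libraries of RNA 3D structure fragments at the
    level of Smallest Secondary Elements (SSEs): stems and the loop classes
    (hairpin, bulge, internal, junction, open loop), each carried together
    with two flanking base pairs of every adjoining stem.  Structures read
    from PDB or mmCIF files are sanitized (modified nucleotides mapped to
    parent bases, fragmentary residues removed, missing heavy atoms completed
    by idealized-residue grafting), base pairs are annotated geometrically,
    secondary structures are derived with conflict filtering and pseudoknot
    removal, and chains are decomposed into SSE records under two schemes
    that differ in the treatment of single-base-pair helices.  A target RNA
    given as sequence plus dot-bracket secondary structure is then assembled
    from library templates by rigid superposition over shared flanking pairs,
    relieved of steric clashes by gradient descent, refined by simulated
    annealing Monte Carlo over rigid moveable elements, and the sampled
    ensemble is clustered on pairwise RMSD to report ranked representative
    models.  A synthetic-fixture generator provides full heavy-atom RNA
    coordinates for arbitrary nested secondary structures so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    cluster,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
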