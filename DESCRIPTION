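Package: nhpi
Title: Geometric Detection and Analysis of Amide NH-pi Interactions in
    Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and characterises NH-pi contacts between side-chain
    amide donors (Gln, Asn, acetamide) and phenyl rings (Phe, toluene) in
    protein structures.  Provides a minimal fixed-column PDB reader/writer,
    a six-parameter description of each donor-ring pair (centroid distance,
    approach angle, N-H...centroid angle, reference-carbon distance, signed
    elevation and in-plane azimuth), distance/angle screening with the
    standard NH-pi cutoffs, collagen triple-helix register classification,
    a Shrake-Rupley solvent-accessible-surface implementation with burial
    classes, ensemble/trajectory analysis (ring superposition, density
    maps, cutoff occupancy), two-state melting-temperature extraction from
    CD curves, and generation of the acetamide-toluene potential-energy
    scan lattice for external quantum-chemistry engines.  A synthetic-data
    module plants donor-ring fragments at prescribed geometry so the whole
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    withr
Config/testthat/edition: 3
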