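Package: chromoclad
Title: Chromosomal Cladistics from Cross-Species Chromosome Painting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for phylogenetic reconstruction from cross-species
    chromosome painting (ZOO-FISH) comparative maps. Validates karyotypes
    (diploid and fundamental numbers), reads painting homology maps, derives
    binary cladistic characters from segmental associations, syntenic
    disruptions and structural rearrangements, runs exhaustive Fitch
    maximum-parsimony searches with nonparametric bootstrap and Bremer decay
    support, classifies every chromosomal change a posteriori as
    autapomorphy, synapomorphy, plesiomorphy or homoplasy, and simulates
    karyotype evolution (fusion, fission, reciprocal translocation,
    pericentric inversion) along a known tree for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
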