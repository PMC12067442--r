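Package: ringamines
Title: Exhaustive Enumeration of Saturated Amine and Diamine Ring Scaffolds
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Generates from first principles every saturated mono- and
    bicyclic carbon ring system whose smallest rings have 5, 6 or 7 members,
    derives all amine and diamine scaffolds by single and double
    nitrogen-feature exchange (ring C to N, and C-H to C-NH2) under chemical
    validity rules excluding hydrazines, aminals and quaternary ammonium
    ions, deduplicates the results up to graph symmetry, and stratifies the
    scaffold counts by ring size, ring topology (monocyclic, spirocyclic,
    fused, bridged) and amine-type profile. Includes molecular formula and
    molecular weight computation, SMILES import and export, and an offline
    novelty-annotation hook against a user-supplied reference list.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
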