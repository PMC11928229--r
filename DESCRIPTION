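Package: charrec
Title: Ontology-Enhanced Authoring of Taxon-by-Character Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless engine for authoring FAIR taxon-by-character
    matrices against a controlled phenotype vocabulary. Provides an
    in-memory ontology model with Turtle load/save and a full term
    lifecycle (minting, deprecation with persistent identifiers,
    replacement chains), tiered resolution of free-text input to
    preferred terms, categorical and numerical character definitions
    with measurement landmarks, units and constraint clauses, a
    decision-tree character recommender, matrix recording with
    certainty/degree modifiers, shared-value reuse and deprecation
    update flags, sRGB colour-palette capture with nearest-colour
    lookup, a typed conflict-resolution queue for expert curation, and
    exports to CSV, TriG knowledge graphs and generated narrative
    descriptions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
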