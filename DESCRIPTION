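Package: physroute
Title: Eliciting Candidate Anatomical Routes for Protein Interactions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A formal theory of physiological communication between body
    compartments and a route-elicitation engine built on it. Given ground
    facts about two proteins (post-production sites, translocation
    capabilities) and a knowledge base of anatomical connectivity, the
    package classifies the interaction scenario (endocrine, colocated,
    unsupported), derives location, exposure and communication facts by
    forward chaining, and elicits a concrete candidate anatomical route
    between the proteins' sites: a raw compartment sequence with boundary
    crossings, a vessel-level condensed path, and the transport-modality
    footprint (diffusion, convection, advection). Includes a deterministic
    generator of synthetic human-circulation knowledge bases and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
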