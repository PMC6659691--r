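Package: mcellsim
Title: Multi-Cell Signaling Network Simulation and Trend Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Builds single-cell signaling-pathway models with Michaelis-Menten
    and mass-action rate laws, integrates them as stiff ordinary differential
    equations with an implicit Radau method, perturbs them with agonist doses
    and genomic lesions (mutations and copy-number variants), composes cell
    models into multi-cell systems coupled through a shared medium compartment
    (autocrine/paracrine signaling) or staged feed-forward input, reads out
    biomarkers as percent change versus a control network, and validates
    predicted against observed response trends with an exact binomial test.
    Ships self-contained seeded fixtures: a G-protein-coupled-receptor cAMP
    pathway, an interferon-gamma JAK/STAT pathway, a three-cell inflammation
    model with ten chemokine/cytokine markers, and a myeloma plus dendritic
    cell pair with divergent genomic profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    xml2,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
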