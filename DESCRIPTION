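Package: edtransfernet
Title: Social Network Analysis of Interhospital Emergency Department Transfers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed valued hospital networks from patient-level
    emergency department (ED) transfer records and computes the social-network
    statistics used to monitor regionalized emergency care: node-level degree,
    net connectivity, standardized betweenness and closeness centrality, and
    local clustering; network-level density, in-degree (Freeman) centralization,
    average clustering, dyad census and dyadic reciprocity. Includes skeleton
    (tie-strength) filtering, per-year network slices, descriptive summaries of
    transfer records, a population/in-degree regression, a distributor-outcome
    comparison, geographic sociogram rendering, and a calibrated hub-and-spoke
    synthetic data generator with a ground-truth ledger so the whole pipeline
    is testable without access to restricted transfer registries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tools,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
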