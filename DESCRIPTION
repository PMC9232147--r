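Package: gtreach
Title: Guarded-Transition Models from BioPAX Pathways and SAT-Based
    Phenotype Controller Search
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Interprets BioPAX Level-3 pathway knowledge into discrete
    guarded-transition models (an extension of Petri nets with Boolean
    guards and shared clock events) and answers phenotype queries by
    bounded, SAT-based reachability. For a query given as a Boolean
    formula over biological entities, the package enumerates the minimal
    sets of boundary entities whose initial activation drives the system
    to the phenotype, together with witness firing schedules and the
    intermediate (trajectory) entities involved. Includes curation of
    BioPAX graphs (duplicate merging, catalyst reification, generic-class
    expansion), structural model reports, trajectory-graph and occupancy
    matrix exports, and seeded synthetic BioPAX generation for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xml2,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Pathways, Network, GraphAndNetwork, Software
RoxygenNote: 7.3.3
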