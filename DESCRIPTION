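Package: gpanet
Title: Geometric Preferential Attachment Networks and Soft Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Grows scale-free, strongly clustered networks in the hyperbolic
    plane by geometric preferential attachment (GPA): each new node chooses
    its angular (similarity) coordinate with probability proportional to the
    local node density plus an initial attractiveness Lambda, then links to
    the hyperbolically closest existing nodes. Provides soft-community
    detection from angular gaps via the critical-gap threshold, community
    separation metrics, degree-distribution diagnostics with native discrete
    power-law fitting, clustering spectra, and Monte-Carlo maximum-likelihood
    inference of Lambda, including temporal profiles over growing network
    prefixes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'gpanet-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'geometry.R'
    'io.R'
    'simulator.R'
    'inference.R'
    'communities.R'
    'netstats.R'
    'cli.R'
    'methods.R'
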