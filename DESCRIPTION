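Package: coevonet
Title: Host-Parasite Coevolution of Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates antagonistic coevolution between a host and a parasite
    population of Wagner-type gene regulatory networks, in which parasite
    fitness rewards phenotype mimicry and host fitness rewards phenotype
    divergence. Provides the sigmoid expression dynamics (genotype-to-phenotype
    map), the two-population evolutionary engine (reproduction, mutation,
    viability selection, lineage tracking), and the full measurement suite:
    per-interaction mutational sensitivity scores over a Gaussian mutation
    grid, mutational and environmental robustness, sign-simplified network
    diversity, Jaccard lability of sensitive interactions with randomization
    nulls, a Dirichlet (string-cutting) null for the spread of sensitivity,
    row and column dominance, Newman modularity with a deterministic greedy
    optimizer, and alternating-phenotype detection. Comparison model variants
    (split stabilizing/coevolutionary selection, discrete expression dynamics,
    and the modularly-varying-goals logic-circuit regime) are included.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    data.table,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
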