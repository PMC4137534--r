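Package: swarmselect
Title: Swarm-Intelligence Wrapper Feature Selection for Binary
    Gene-Expression Classification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage gene selection for binary cancer classification from
    microarray-style expression matrices.  Genes are first ranked by a
    per-gene filter statistic (Welch-style T-statistic, signal-to-noise
    ratio, or the between-class variance ratio F), then the top-m candidate
    genes are searched by one of four population-based metaheuristics --
    particle swarm optimization, cuckoo search, shuffled frog leaping, and
    shuffled frog leaping with Levy-flight steps -- using k-nearest-neighbour
    cross-validated accuracy as the fitness function.  Includes delimited-text
    dataset I/O, a seeded synthetic-data generator with planted
    differentially expressed genes, a grid-running pipeline and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
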