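Package: spermtopo
Title: Chromosome Topology Analysis in Human Sperm Nuclei
Version: 0.1.0
Authors@R:
    person("spermtopo", "developers", email = "spermtopo@example.org",
           role = c("aut", "cre"))
Description: Quantifies the nuclear topology of centromeres in human sperm from
    multi-channel FISH/IF microscopy images or per-signal coordinate tables.
    Implements the classical sperm-nucleus coordinate model: linear (a/m/b)
    zoning along the longitudinal axis, normalized radial positioning (D/L,
    H/L) with mirror folding, shape-based quality control, inter-centromere
    distances, Ward clustering of chromocenters with Newick dendrogram export,
    immunofluorescence-based 5mC/5hmC stratification, chromatin-class
    (aniline blue / acridine orange / TUNEL) frequency tables, and the
    accompanying hypothesis-testing policy (Shapiro-Wilk gated Mann-Whitney /
    Welch t, Kruskal-Wallis with Dunn's post hoc). A seeded synthetic-data
    generator produces coordinate tables and rendered images with known ground
    truth so that every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
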