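Package: ictalnet
Title: Time-Resolved Functional Connectivity Network Analysis of Intracranial Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds time-varying functional connectivity networks from
    multichannel intracranial electrophysiology (sliding-window Pearson
    correlation with temporal smoothing and negative-weight rectification),
    computes seven weighted graph statistics per network (density, clustering
    coefficient, characteristic path length, assortativity, Newman spectral
    modularity, spectral radius, Laplacian synchronizability), and compares
    seizure types over time with a seizure-level bootstrap, shuffled-label
    permutation nulls, doubled one-tailed p-values, Cohen's d summaries,
    5-minute windowed averages and repeated-measures ANOVA. Includes a
    seeded synthetic multichannel ECoG generator with community-structured,
    time-varying coupling for the three study conditions (focal-remaining-
    focal, focal-to-bilateral, interictal), plus EDF+ and CSV/JSON
    input/output and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    igraph,
    car,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
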