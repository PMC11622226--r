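Package: msipca
Title: Memory-Bounded Incremental PCA for Mass Spectrometry Imaging Datacubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Out-of-core principal component analysis for peak-picked mass
    spectrometry imaging (MSI) data stored as flat binary float32 datacubes.
    Implements the sequential Karhunen-Loeve incremental PCA update with
    running mean/variance accumulation, a batch-size heuristic tied to the
    number of mass peaks, incremental score transformation, exact and
    pixel-subsampled PCA comparators with sign-aligned accuracy metrics
    (MSE, r-squared, percent-of-range differences, principal angles),
    a synthetic MSI datacube generator with planted low-rank spatial
    structure, hyperspectral RGB rendering of principal components, a
    command-line front end, and resident-memory benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    dplyr,
    ggplot2,
    generics,
    png,
    rlang,
    xml2,
    optparse,
    parallel,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
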