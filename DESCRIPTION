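Package: trajspace
Title: 3D Pseudospace-Time Trajectories from Serial Spatial Transcriptomics Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs 3D global pseudospace-time trajectories from serial
    planar spatial transcriptomics sections (Visium-style spot data with
    anatomical region annotations). Computes diffusion pseudotime per section
    from a root region, extracts planar region-level trajectories, merges them
    across sections into 3D trajectories with support-based filtering, ranks
    Spearman transition genes per subtrajectory and unions them across sections
    with a signed max-absolute-value conflict rule, builds cell-subtype marker
    profiles and sign-aware similarities across time points, matches profiles
    to cell types in a local marker database by hypergeometric enrichment,
    scores ligand-receptor communication density per trajectory against a
    spatial permutation null, and compares densities across time points with
    the Kruskal-Wallis test. Ships a synthetic multi-section data generator
    with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
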