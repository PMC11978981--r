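Package: coldsplit
Title: Leakage-Reduced Data Splitting for Biomolecular Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes train/validation/test splits of one- and two-dimensional
    biomolecular datasets that minimize similarity-induced information leakage.
    The split is posed as a constrained combinatorial optimization problem:
    minimize the total cross-fold pairwise similarity subject to split-fraction
    and stratification constraints, solved exactly by integer linear
    programming on small instances and by a cluster-then-solve heuristic
    (spectral or agglomerative clustering, linkage reduction, ILP on the
    reduced instance, unpacking) on large ones. Includes Tanimoto similarity
    on Bemis-Murcko scaffold fingerprints for small molecules, user-provided
    similarity or distance matrices for other entity types, stratified and
    random baseline splitters, interaction-table assignment with discarding
    for two-dimensional (e.g. drug-target) data, and synthetic fixture
    generators with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    generics,
    ggplot2,
    kernlab,
    withr,
    optparse,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
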