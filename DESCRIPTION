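Package: virtualcohort
Title: Virtual Patient Cohort Generation with Bayesian Gaussian Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates large-scale synthetic tabular cohorts of virtual
    patients from a real clinical dataset. A curation stage splits features
    into eligible and non-eligible sub-spaces by missingness, flags outlying
    patients with isolation forests, removes duplicated features by
    correlation and by name similarity, and imputes missing values by
    k-nearest neighbours. The number of Gaussian components is then estimated
    by spectral clustering with a locally optimal block preconditioned
    conjugate gradient (LOBPCG) eigensolver, scored over a range of cluster
    counts with the Davies-Bouldin index. A truncated stick-breaking
    Dirichlet-process Gaussian mixture is fitted by variational inference
    with the weight-concentration parameter set to exp(-opt), and arbitrarily
    many virtual patients are sampled from the posterior. Fidelity of the
    synthetic cohort is scored with five indicators: coefficient-of-variation
    difference, inter- and intra-correlation differences, a
    Kolmogorov-Smirnov goodness of fit, and histogram Kullback-Leibler
    divergence, with kernel-density overlays per feature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
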