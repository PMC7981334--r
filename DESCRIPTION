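Package: fcaging
Title: Aging Effects on Functional Connectomes, D1 Receptor Availability
    and Gray Matter Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how aging reshapes functional connectomes in
    two-age-group neuroimaging cohorts. Builds Fisher-z functional
    connectomes from ROI-level BOLD time series with motion scrubbing,
    nuisance regression and band-pass filtering; fits a per-connection
    heteroscedastic location-scale age model (linear age effects on the mean
    and on the log standard deviation, with a head-motion covariate) by
    maximum a posteriori estimation with weakly informative priors;
    quantifies connectome similarity, classical multidimensional scaling
    embeddings and connection-removal contribution curves; estimates D1
    receptor binding potential from PET time-activity curves by Logan
    reference-tissue graphical analysis; and relates nodal aging effects
    across functional connectivity, binding potential and gray matter
    density. A synthetic-data module generates cohorts, ground-truth edge
    and node parameters, motion-contaminated ROI time series, simplified
    reference tissue model time-activity curves and gray matter density
    tables so the whole analysis is exercisable without access to scanner
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
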