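Package: pcnmepi
Title: Spatial Eigenvector Modelling of Disease Incidence Rates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds principal coordinates of neighbor matrices (PCNM,
    the Euclidean-distance special case of Moran's eigenvector maps) from
    planar site coordinates alone, and models area-level disease incidence
    rates on the resulting spatial eigenvectors by forward-selected ordinary
    least squares under a double stopping criterion (alpha-to-enter plus an
    adjusted r-squared ceiling taken from the all-vector model).  Includes
    population-weighted settlement centroids, minimum-spanning-tree distance
    truncation, Moran's I diagnostics, pooled incidence rates per 1,000
    person-years with a Kolmogorov-Smirnov normality gate and log10
    transform, studentized-residual and Chauvenet outlier reports, a
    synthetic-scenario generator for method evaluation, and a command-line
    pipeline over delimited-text inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    withr
Config/testthat/edition: 3
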