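Package: rsindex
Title: Resilience to Stress Index from Multichannel Psychophysiological Recordings
Version: 0.1.0
Authors@R:
    person("rsindex", "maintainers", email = "maintainers@rsindex.org", role = c("aut", "cre"))
Description: Computes cohort-relative resilience indices from five-channel
    psychophysiological recordings (electromyography, blood volume pulse,
    breathing, skin conductance, peripheral temperature) collected during a
    phased stress-test protocol. Provides signal conditioning (offset trim,
    median filter, standardization, Yeo-Johnson power transform, block-median
    downsampling), differenced feature construction, four inter-phase
    cluster-distance methods (Euclidean distance of principal components,
    Mahalanobis distance, silhouette-based cluster validity index, kernel
    PCA), the Resilience to Stress Index (RSI) and Alteration Factor (AF),
    the associated statistical validation workflow (Anderson-Darling gate,
    Pearson/Spearman correlation, Friedman comparison), and a synthetic
    cohort simulator with ground-truth recovery parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
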