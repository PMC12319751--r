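Package: micica
Title: Automated Speech-Artefact Removal from MEG Using EMG Mutual Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies and removes myogenic speech artefacts from
    magnetoencephalography (MEG) recordings. Independent component analysis
    (FastICA with PCA pre-whitening at an explained-variance threshold) is
    applied to planar-gradiometer data; artefactual components are detected by
    their Kraskov k-nearest-neighbour mutual information with the principal
    components of co-recorded facial surface EMG, normalized to a mutual
    information correlation coefficient, and elected by k-means clustering of
    the per-component MI profiles. Removal is evaluated with root-mean-square
    deviation maps of evoked responses and sensor-level cluster-based
    permutation tests. A synthetic generator reproduces the facial-gesture and
    picture-naming paradigms with planted ground-truth artefact sources, so the
    whole pipeline can be exercised and validated without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    arrow,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
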