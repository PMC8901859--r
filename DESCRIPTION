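Package: v1sync
Title: Visual Responsiveness, Population Synchrony and Morphometrics for V1 Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-photon calcium imaging of mouse primary
    visual cortex (V1) together with a concurrent piezo-based behavioral
    readout (the visually induced fidget, or "vidget") and dendritic
    morphometrics. Implements ROI trace extraction and dF/F0 transient
    detection, stimulus-responsiveness classification and the neural activity
    index (NAI), n-order population synchrony with a count-preserving
    Monte-Carlo shuffle null, pairwise correlation of deconvolved spontaneous
    activity and its spatial (distance-binned) structure, a random k-subgroup
    nearest-neighbor-distance dispersion statistic, vidget scoring with
    piecewise-linear cumulative-magnitude fitting, and a dendritic-complexity
    metric on SWC reconstructions. A synthetic-data generator with known
    ground truth stands in for animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
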