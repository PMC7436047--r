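Package: rsifreg
Title: Globally Optimal Similarity Point-Set Registration by Transformation
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the 7-DoF similarity transformation (scale, rotation,
    translation) aligning two 3D point sets without initialization or known
    correspondences. The transformation is decomposed: translation is found
    first by branch-and-bound consensus maximization over rotation-and-scale-
    invariant features (angle triples of point triples), rotation is then
    found by a second branch-and-bound over the axis-angle ball, and scale is
    finally taken as the median of norm ratios over the consensus
    correspondences. Includes interval-arithmetic bounds with soundness
    certificates, a synthetic benchmark generator (gross outliers, missing
    points), sweep protocols with success-rate reporting, target registration
    error evaluation, and PLY/XYZ/CSV point-cloud I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
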