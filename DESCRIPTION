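Package: hevquant
Title: Quantification of 3D High Endothelial Venule Networks from
    Light-Sheet Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to segment PNAd-labelled vessel signal in cleared-tissue
    light-sheet stacks, reduce it to a topology-preserving medial skeleton,
    extract an attributed vessel graph (junction and endpoint nodes, traced
    segments, physical lengths and distance-transform widths, discrete
    networks), and summarise the network as the numerical descriptors and
    binned length/width distributions used in lymph-node HEV remodelling
    studies.  Also provides 2D section-based HEV metrics with the HEVhi/HEVlo
    median split, caliper tumor volume and exponential growth-rate fitting,
    Amira SpatialGraph export for external rendering, and synthetic vascular
    phantoms with exact ground-truth topology for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
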