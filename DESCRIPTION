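Package: neovb
Title: Searchlight Vogt-Bailey Mapping of Neonatal Cortical Microstructure
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Computes per-vertex Vogt-Bailey (VB) indices of local cortical
    feature homogeneity from multi-channel diffusion-derived microstructure
    volumes (FA, MD, AD, RD and tissue-fraction-modulated NDI/ODI), using a
    hybrid surface-to-volume searchlight restricted to a 27-voxel cube.
    Includes Gaussian-weighted geodesic smoothing of surface maps, vertex-wise
    general linear models with Freedman-Lane permutation inference,
    threshold-free cluster enhancement and familywise error correction, and a
    synthetic-cohort generator with planted regional homogeneity effects for
    end-to-end validation. Reads and writes GIFTI surfaces and metrics and
    NIfTI volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    withr,
    xml2
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
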