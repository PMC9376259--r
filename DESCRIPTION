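Package: surfmvpa
Title: Surface-Space Searchlight MVPA for fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Surface-space-based multivariate pattern analysis (sf-MVPA) of
    fMRI data on triangulated cortical meshes. Provides the double-radius
    dividing algorithm for downsampling a vertex-level surface into
    approximately uniform labels, label-space searchlight construction,
    frame-by-frame cross-validated multiclass decoding with linear support
    vector machines, second-level random-effects inference with
    Benjamini-Hochberg false discovery rate control and recursive
    cluster-extent extraction, hemodynamic-response-function based general
    linear model response-strength estimation with load regression, and
    seed-based trial-wise functional connectivity analysis. Includes readers
    and writers for FreeSurfer binary surfaces, curv overlays and annot
    parcellations as well as GIFTI arrays, and a synthetic BOLD generator
    emulating a multi-run working-memory paradigm for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
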