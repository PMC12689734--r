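Package: skelreg
Title: Skeleton-Feature Registration of Cross-Source Vascular Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rigid registration of vascular point clouds reconstructed from
    different imaging sources, such as a preoperative CT scan and an
    intraoperative ultrasound sweep of the liver.  Both clouds are reduced to
    homologous skeleton feature curves: Laplacian-based point-cloud contraction
    produces a coarse curve skeleton, a Euclidean minimum spanning tree with
    degree-classified nodes splits it into branches and trunks, and robust
    recalculated centre points are fitted with quadratic curves.  The feature
    curves are aligned in two stages, a globally optimal branch-and-bound ICP
    for coarse alignment followed by a fine ICP stage.  The package also
    provides the evaluation metrics used in image-guided ablation studies
    (skeleton RMSE, tumour-centre target registration error, Dice, volume
    similarity, surface Dice at tolerance), point-cloud input/output in PLY,
    PCD and XYZ formats, a synthetic branching-vessel phantom generator with
    known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
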