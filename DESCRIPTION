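Package: retinotype
Title: Visual Response Typing and Retina-to-Tectum Input Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for functional typing of visual responses in
    the larval zebrafish optic tectum and for decomposing tectal responses
    into retinal ganglion cell (RGC) inputs. Builds calcium-kernel-convolved
    stimulus regressors, computes per-unit response scores (regression
    coefficient times squared correlation within a response window),
    clusters response types by affinity propagation followed by
    hierarchical clustering with silhouette-based threshold selection,
    transfers labels by k-nearest neighbors, and fits non-negative
    L1-regularized linear models of tectal scores on RGC cluster averages.
    Also includes laminar morphometry of SWC neuron tracings against a
    layer atlas and prey-capture behavior statistics (swim-bout
    segmentation, eye-convergence thresholding, J-turn direction
    selectivity). A synthetic-data module generates every input with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    stats,
    tools,
    utils,
    yaml
Suggests:
    glmnet,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
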