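Package: aesthseq
Title: Feature Analysis and Psychophysical Validation of Aesthetic Image
    Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying which low- and mid-level image features
    track the aesthetic value of images arranged in sequences indexed by a
    steering parameter alpha.  The package generates synthetic
    alpha-indexed RGB image sequences with controllable feature slopes,
    computes seven image features (brightness, contrast, Laplacian
    sharpness, saturation, Hasler-Suesstrunk colorfulness, quadtree
    complexity and quadtree symmetry), simulates and cleans
    two-alternative forced-choice preference experiments, fits
    psychometric functions with free guess and lapse rates, relates
    features to alpha and to aesthetic scores by least-squares and ridge
    regression, and screens sequences by feature stability, aesthetic
    downturn, and the Frechet distance between Gaussian summaries of
    image embeddings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
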