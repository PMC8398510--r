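Package: rehabrec
Title: Activity Recognition for Upper-Limb Rehabilitation from Wrist-Worn Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Recognizes upper-limb rehabilitation exercises from continuous
    tri-axial wrist acceleration recordings. The pipeline smooths raw signals
    with a moving-average filter, segments individual exercise repetitions
    dynamically from peaks and valleys of the acceleration magnitude (so
    segment length tracks repetition duration), extracts 24 time-domain
    features per repetition, classifies repetitions into seven shoulder and
    elbow exercises with SVM, k-nearest-neighbour, random-forest or Gaussian
    naive-Bayes models, and evaluates with leave-one-subject-out
    cross-validation. A fixed-length sliding-window segmenter is included as
    the conventional baseline, and a seeded synthetic-study generator
    produces labeled recordings emulating a ten-subject exercise protocol so
    the full pipeline can be exercised end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
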