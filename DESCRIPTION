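Package: flatfootr
Title: Flat-Foot Severity Assessment from Lateral Weight-Bearing Foot
    Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated grading of pes planus (flat foot) from lateral
    weight-bearing foot radiographs. Nine anatomical landmarks (points of
    interest on the calcaneus, talus, first and fifth metatarsals, and
    sesamoid) are localized by normalized squared-difference template
    matching followed by random-forest re-ranking of candidate patches;
    three clinical angles (calcaneal inclination angle, Meary's angle, and
    the arch angle) are measured from the landmarks, classified against
    published degree intervals, and combined by majority vote into a
    normal / mild / moderate diagnosis. A synthetic radiograph phantom
    generator with exact ground-truth landmarks and angles makes the whole
    pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    ggplot2,
    generics,
    jsonlite,
    png,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
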