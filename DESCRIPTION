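Package: cowcollar
Title: Collar-Sensor Analytics for Cattle Behaviour, Step Counting and
    Skin Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for wearable collar sensors on cattle:
    rolling-median smoothing and error analysis of infrared skin-temperature
    traces against a rectal baseline, sliding-window feature extraction from
    9-channel inertial measurement unit (IMU) streams, multi-classifier
    behaviour classification scored by per-class sensitivity and precision,
    and binary support-vector-machine step counting.  A seeded semi-Markov
    simulator generates behaviour-annotated synthetic collar datasets (IMU,
    skin temperature, ground-truth step events) so that every stage of the
    pipeline can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    e1071,
    randomForest,
    nnet,
    rpart,
    class,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
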