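Package: ictal
Title: Machine Learning Seizure Detection and Quality Indices for ECT EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing electroencephalograms recorded during
    electroconvulsive therapy (ECT). Recordings are partitioned into fixed
    1.28 s windows, classified as ictal or non-ictal by cross-validated,
    MCC-tuned machine-learning models, and the resulting probability traces
    are converted into seizure onset and endpoint annotations. From an
    annotated record the package derives the eight seizure quality indices
    used in clinical ECT practice (seizure duration, postictal suppression
    index, average seizure energy index, maximum sustained power, time to
    peak power, early- and mid-ictal amplitude, and maximum sustained
    interhemispheric coherence), together with the agreement statistics
    (Spearman, Mann-Whitney, ICC3/ICC3K) used to validate them against
    reference systems. A synthetic ECT-EEG simulator with known ground
    truth makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    rpart,
    randomForest,
    class,
    xgboost,
    pROC,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
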