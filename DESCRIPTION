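Package: classtalk
Type: Package
Title: Social Interaction Detection and Child-Directed Speech Measures
    from Egocentric Classroom Feature Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects a focal child's social interactions with adults and
    peers from audiovisual feature streams derived from head-mounted
    camera recordings in preschool classrooms, and quantifies the
    child-directed speech (CDS) occurring within those interactions.
    Provides a synthetic classroom-session simulator, fixed-rate (250 ms)
    feature building with occlusion infilling, bi-directional LSTM
    sequence classifiers trained per partner class, interval smoothing,
    utterance diarization by interval overlap, transcript measures (TNU,
    TNW, NDW, MLU, TTR) with 10-minute norming, leave-one-subject-out
    validation, and ordinary-least-products calibration of raw automatic
    measures against reference transcription.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
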