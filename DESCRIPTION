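Package: faceAOI
Title: Automated Face Area-of-Interest Annotation for Mobile Eye-Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds face areas-of-interest (AOIs) from head keypoints
    produced by a pose detector, classifies per-40-ms face-gaze from
    wearable eye-tracker gaze samples, assigns person identities by
    Euclidean nearest-neighbour matching against a labelled embedding
    gallery, and scores agreement between annotation timelines with
    Cohen's kappa, frame-by-frame accuracy, face-gaze durations and
    normalized differences. Includes a synthetic-scene generator that
    produces keypoint tracks, gaze samples, embeddings and ground-truth
    timelines for end-to-end validation, plus readers and writers for
    the plain-text file dialects and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
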