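Package: euscv
Title: Patient-Grouped Cross-Validation for Endoscopic Ultrasound Image
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A leakage-safe cross-validation framework for differentiating
    two classes of pancreatic lesions (pancreatic ductal adenocarcinoma
    versus localized autoimmune pancreatitis) on grayscale endoscopic
    ultrasound video frames.  Patients are ordered by a clinical factor
    (session chronology, age, BMI, alcohol intake, or endoscopists'
    diagnostic accuracy), divided into five patient groups either as
    contiguous "ordered" blocks or round-robin "balanced" strides, and all
    20 test/validation role allotments are trained and evaluated.  Three
    temporally distinct frames of one patient are stacked into a quasi-RGB
    image, features are taken from a frozen extractor, a logistic
    classification head is trained with best-validation-AUROC
    checkpointing, and per-patient predictions are the mean of median-of-4
    ensemble scores.  Includes a seeded synthetic speckle-image cohort
    generator with a simulated endoscopist rater panel, the full
    ROC/confusion-matrix evaluation suite with exact rank-sum and Fisher
    tests, and occlusion sensitivity maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
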