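Package: melasmaGABP
Title: Melasma Treatment-Effect Evaluation with a GA-Initialized Backpropagation Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clinical severity scoring and neural-network evaluation of melasma
    laser-treatment outcomes. Implements the Melasma Area and Severity Index
    (MASI), its decline rate and four-grade efficacy classification, ordinal
    grading of five reflectance-confocal-microscopy (RCM) parameters, a
    from-scratch three-layer sigmoid perceptron trained by gradient descent, a
    real-coded genetic algorithm that searches the weight space to seed
    backpropagation (GA-BP), a synthetic patient-cohort generator with the
    cohort structure the analysis assumes, and an experiment runner that
    compares plain BP against GA-BP over paired simulation seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
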