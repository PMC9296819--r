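Package: metadecode
Title: Meta-Learning Sample Reweighting for Neural Decoding with Noisy Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains multilayer-perceptron decoders of behavioural variables
    from neural-activity features when training labels are noisy, by
    meta-learning a non-negative weight for every training sample each
    optimisation step so that a one-step updated model minimises the loss on a
    small, clean validation set. Includes a leaky integrate-and-fire
    population simulator that generates imbalanced binary decoding tasks, a
    label-shuffling noise model with mislabel bookkeeping, class-imbalance
    aware evaluation (F1, balanced accuracy, rank-sum weight-separation
    analysis), and experiment runners for noise sweeps, validation-size
    sweeps, pooled mixed-quality training sets, and trial-trajectory
    (calcium-imaging-style) decoding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
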