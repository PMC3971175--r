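Package: aitrust
Title: Active-Inference Agents for the Iterated Trust Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates interpersonal exchange as discrete-state active
    inference. An agent ("self") plays an iterated two-choice Trust game
    against a naive partner whose prosocial or antisocial disposition
    ("esteem") is a hidden trait. Goals enter as softmax prior beliefs over
    outcomes, policies are scored by the Kullback-Leibler divergence between
    predicted and desired outcome distributions, and beliefs about states,
    policies and the precision (inverse temperature) of policy selection are
    updated by variational message passing under a gamma precision prior.
    Includes the generic model algebra, the Trust-game construction with
    esteem-augmented utilities, the variational engine, an iterated-play
    driver with posterior-to-prior carry-over, configuration and trace I/O,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
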