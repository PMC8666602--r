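Package: loopflow
Title: Information Flow Decomposition in the Sensorimotor Loop
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how the complexity of a task is distributed between
    the brain, body and environment of an embodied agent. Provides exact
    algebra for discrete probability tables over the sensorimotor loop, a
    kinematic simulator of a two-wheeled agent with binary whisker sensors on
    a closed racetrack, Monte-Carlo estimation of the intrinsic sensor and
    goal channels, planning-as-inference policy optimization via the
    expectation-maximization algorithm, and seven KL-projection information
    flow measures (integrated information, morphological computation,
    reactive control, action effect, sensory information, control and total
    information flow), together with sweep orchestration over sensor lengths
    and controller architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
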