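Package: socdiff
Title: Network-Based Diffusion Analysis of Social Transmission in Animal Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Order-of-acquisition network-based diffusion analysis (OADA) for
    open-diffusion experiments, with dynamic observation networks, multi-model
    AICc inference, profile-likelihood confidence intervals for the social
    transmission parameter, conversion to the estimated percentage of learning
    events attributable to social transmission, a multistate (naive ->
    interacting -> informed) extension, a self-contained Bayesian logistic
    mixed model for observation-network structure, and a discrete-event
    simulator of diffusion experiments with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
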