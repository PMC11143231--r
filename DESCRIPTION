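Package: genecircuit
Title: Deterministic Models of Single-Gene Autoinhibitory Circuits with
    Explicit Promoter Kinetics and Delays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A family of deterministic models of a single gene that represses
    its own transcription, spanning description levels from the two-variable
    instantaneous model to multi-stage elongation chains, Gamma (Erlang)
    distributed-delay and discrete-delay variants, and models with explicit
    mass-action kinetics of a three-site cis-regulatory system under two
    cooperative transcription-factor binding mechanisms (recruitment and
    stabilization). Provides the Adair and Hill regulatory functions and the
    mapping from binding kinetics to effective phenomenological parameters
    (apparent dissociation constant and Hill exponent), exact linear-chain-trick
    expansion of Erlang delay kernels, numerical integration of the ordinary and
    delay differential systems, linear stability analysis including rightmost
    roots of transcendental characteristic equations, Hopf-threshold scans,
    oscillation quantification (period, amplitude, sustainedness), and a
    registry of reference parameter regimes for reproducible scenario runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
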