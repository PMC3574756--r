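Package: gwimmune
Title: Stochastic Galton-Watson Models of Within-Host Pathogen-Immune Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact distribution-propagating simulator for multitype
    Galton-Watson branching processes with multiplication, mutation,
    selection and a carrying-capacity cut-off, applied to within-host
    pathogen-immune dynamics. Propagates whole probability distributions
    (including the extinction probability) generation by generation for a
    single replicating entity, a two-type mutation process, a pathogen
    coupled to an effector/memory immune system through threshold step
    functions, a two-strain antigenically variable pathogen facing two
    specific immune arms, and a four-type T-lymphocyte maturation process.
    Ships an agent-level Monte-Carlo oracle, deterministic logistic and
    two-species ODE comparators with least-squares rate fitting, and canned
    scenario configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
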