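Package: filehne
Title: Bayesian Stationarity-Prior Observer Model of Tactile Motion
    Perception During Pursuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a Bayesian ideal-observer model of tactile surface-motion
    perception during manual pursuit, in which noisy proprioceptive and cutaneous
    velocity measurements are each combined with a zero-mean stationarity prior
    and then summed, producing a pursuit-dependent motion bias (a tactile analog
    of the visual Filehne illusion). Provides closed-form psychometric
    predictions (PSE, JND, Filehne gain), a pin-array apparent-motion stimulus
    timeline simulator, synthetic two-alternative experiments with heterogeneous
    observers, probit psychometric fitting at the individual and hierarchical
    (mixed-effects) level, parametric-bootstrap confidence intervals, likelihood
    ratio tests on psychometric slopes, and constrained maximum-likelihood
    fitting of the observer model with a parametric-bootstrap population
    procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
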