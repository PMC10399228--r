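Package: gravadapt
Title: Memory-Augmented Particle-Filter Model of Orientation Perception
    Adaptation to Altered Gravity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates how human orientation perception adapts, and
    re-adapts, when the magnitude of gravity changes (for example during
    spaceflight gravity transitions or centrifugation). A bank of
    vestibular observer models, each conditioned on a hypothesised gravity
    magnitude, converts semicircular-canal and otolith afference into
    sensory-conflict signals. A Rao-Blackwellized particle filter weighs
    the hypotheses by a normalized-innovation-squared likelihood and draws
    new hypotheses from a mixture transition kernel: a short-term Gaussian
    "jitter" search whose width widens when recent likelihoods collapse,
    plus a long-term memory of previously harmonious gravity levels. The
    long-term component reproduces the faster re-adaptation to familiar
    gravity levels reported for repeat flyers, and the central observer
    reproduces the G-excess tilt overestimation during unadapted
    hyper-gravity exposure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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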