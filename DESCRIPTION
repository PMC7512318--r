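Package: nmlcodes
Title: Normalized Maximum Likelihood Codes as Generative Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying minimum description length (MDL) universal codes
    as generative models of discrete data. Implements the normalized maximum
    likelihood (NML) distribution for the Dirichlet (categorical) model, for
    independent-spin (paramagnet), pairwise-coupled (Sherrington-Kirkpatrick)
    and restricted Boltzmann machine models, together with the empirical
    resolution and relevance statistics that characterise their typical samples,
    the maximally-informative-sample frontier, and the exponentially tilted
    ensembles and scaled cumulant generating function that exhibit the
    second-order localization transition of the coding cost at zero tilt.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
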