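Package: cpforage
Title: Spatially Explicit Bioenergetic Simulation of a Marine Central Place Forager
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An individual-based, spatially explicit simulator of a marine
    central place forager: a lactating otariid female alternating foraging
    trips at sea with shore visits to suckle her pup over a 120-day rearing
    season. The package generates artificial prey landscapes as thresholded
    Gaussian random fields with controlled abundance, aggregation and
    distance to the resource; simulates hourly movement (correlated random
    walk, gradient following and memory-directed transit), fishing decisions,
    full energy budgets with drag and satiation, and probabilistic
    starvation mortality of mother and pup; and provides a factorial
    experiment layer with breeding-success statistics, the energetic
    cost/benefit ratio, and bootstrap estimation of the optimal female body
    length as a function of distance to the resource.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
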