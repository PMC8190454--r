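Package: plasmidfate
Title: Evolutionary Dynamics of Chromosomal Versus Plasmid-Borne Gene Location
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing why bacterial genes such as antibiotic
    resistance determinants reside on plasmids rather than chromosomes.
    Implements a six-cell-type compartmental model of competition between
    resistant and sensitive chromosomes and plasmids with conjugative
    transfer and segregation loss; analytic equilibria and linear stability
    analysis with regime classification over parameter space;
    basin-of-attraction mapping that exposes positive frequency-dependent
    selection and the resulting priority effect; structural model variants
    (immigration/local adaptation, plasmid-chromosome gene flow, fluctuating
    antibiotic pressure, alternative cost, killing and segregation terms);
    and a stochastic multispecies model of resistance-gene acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
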