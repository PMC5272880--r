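Package: labmarkov
Title: Multi-State Markov Models of Labour-Market Transitions from Register Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing transitions between the labour-market states
    Jobless, Self-sufficient, Disabled, and Censored in annual
    administrative-register data. Classifies person-years into nine
    labour-market positions and collapses them to four mutually exclusive
    states with absorbing censoring, builds person-period transition panels at
    unequally spaced follow-up years, estimates first-order Markov transition
    models by from-scratch multinomial-logit maximum likelihood (Newton-Raphson
    with analytic gradient and Hessian), and converts fitted or published
    odds ratios into stratified four-way transition-probability tables. A
    seeded synthetic register generator with known ground-truth dynamics makes
    every stage testable without access to the original registers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
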