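Package: aedcover
Title: Simulation of Public-Access Defibrillator Coverage on Urban Road Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study out-of-hospital cardiac arrest (OHCA) response on
    urban street networks. Generates synthetic grid cities with one-way
    streets, computes mode-aware shortest travel times, models ambulance
    one-way response against bystander round-trip retrieval of an automated
    external defibrillator (AED) under a fixed time budget, sites AEDs with
    greedy and exact solvers for the maximal covering location problem
    (MCLP), and compares the two response arms with an exact Wilcoxon
    signed-rank test after a Shapiro-Wilk normality check. Includes
    Cronbach's alpha for Likert-scale usability surveys, GeoJSON/CSV
    input-output, and a fully reproducible end-to-end experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
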