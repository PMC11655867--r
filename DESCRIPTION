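Package: immunocarto
Title: Immune Gene-Module Scoring and Diagnostic Cartography for
    Inflammatory Skin Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to profile inflammatory skin biopsies with targeted
    immune gene panels (NanoString nCounter style counts): two-step
    positive-control and housekeeping normalization, one-vs-rest
    discovery of disjoint immune gene modules (Th1, Th2, Th17, type I
    interferon, neutrophilic, macrophagic, eosinophilic), module and
    activation scoring with bimodal threshold fitting, dominance and
    co-dominance calling, a sentinel reference cartography for
    classifying ambiguous cases such as erythroderma, and matching of
    dominant modules to targeted-therapy mechanisms. Includes a
    negative-binomial cohort simulator with planted module structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
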