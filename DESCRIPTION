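Package: tieredmix
Title: Tiered Mixture Risk Assessment for Co-Occurring Food Contaminants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tiered risk assessment of combined dietary exposure
    to co-occurring food contaminants such as mycotoxins. Derives
    toxicological reference values from reference points and assessment
    factors, computes per-individual long-term dietary exposure with the
    observed-individual-mean model under lower/medium/upper-bound treatment
    of left-censored concentration data, combines exposures across
    compounds by reference-value scaling or by relative potency factors
    from a simultaneous benchmark-dose analysis of continuous endpoints
    (exponential and Hill families, model averaging, parametric bootstrap
    confidence intervals), and characterises combined risk at chosen
    percentiles with bootstrap uncertainty. Includes a seeded synthetic
    data generator emulating total-diet-study concentration data and
    food-consumption diaries so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
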