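Package: physioflux
Title: Quantitative Physiology and C-mol Flux Accounting for Bioreactor Cultivations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates specific growth rates, yields and specific
    consumption/production rates from batch and chemostat bioreactor
    time-series, converts them into C-mol flux maps with carbon-balance
    closure diagnostics and a respiration partition, evaluates weak-acid
    speciation and ATP cost ledgers for alternative acetate/acetyl-CoA
    routes including the phosphoketolase bypass, solves a two-substrate
    gas-flux mixing model, and tests metabolite-panel fold-changes with
    Welch's t-test. Ships a synthetic-data generator for bioreactor series
    and replicate metabolite panels so every pipeline stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
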