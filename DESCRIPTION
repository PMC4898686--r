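Package: floodcarbon
Title: Fine-Scale Financial Comparison of REDD+ and Oil-Palm Conversion in
    Floodplain Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing where avoided-deforestation carbon payments
    (REDD+) financially out-compete conversion of tropical floodplain forest
    to oil palm. Converts tree inventories to above-ground carbon via a
    DBH/wood-density allometry, assigns categorical carbon classes and
    performs mid-point carbon-stock accounting with land-tenure breakdowns,
    builds time-averaged oil-palm carbon reference levels from partially
    observed per-palm age series, evaluates 25-year discounted cash-flow
    models for REDD+ (upfront and staggered payment stances) and for
    oil-palm new plantings under multiple carbon prices and discount rates,
    and allocates each landscape stratum to its higher-value land use with
    roll-ups of area, carbon, CO2-equivalent and required carbon finance.
    Includes a synthetic-landscape generator so the full pipeline is testable
    without external spatial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
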