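Package: fingaps
Title: Financing Gaps Framework for Allocating Development Assistance for Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a financing-gaps framework for allocating development
    assistance for health (DAH). For each country the package estimates the
    resources Needed (N) to reach a health goal via a log-linear under-five
    mortality regression, a goal-compliant annual-rate-of-reduction trajectory
    and a cost-per-life-saved schedule; Expected domestic spending (ES) from a
    child-health expenditure-share regression; and Potential domestic spending
    (PS) from an output-oriented, variable-returns-to-scale data envelopment
    analysis frontier of government health expenditure in GDP per capita.
    Donor funds are then allocated by DAH = alpha[(N - PS) + beta(PS - ES)],
    with budget-normalised allocation and ranking comparisons. A seeded
    synthetic country-panel generator with known generating parameters makes
    every stage testable by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
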