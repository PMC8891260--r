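Package: vaxtea
Title: Techno-Economic Assessment of Pandemic-Response Vaccine Manufacturing Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A transparent, tested pipeline for comparing adenovirus-vectored
    (AVV), messenger RNA (mRNA) and self-amplifying RNA (saRNA) vaccine
    production platforms under uncertainty. Encodes the platform input-factor
    uncertainty model (triangular/uniform factors sampled with a Sobol
    low-discrepancy sequence), a lumped calibrated batch production and cost
    model yielding eight techno-economic key performance indicators,
    variance-based global sensitivity analysis (Saltelli/Jansen Sobol indices
    with bootstrap confidence intervals and an RS-HDMR polynomial metamodel),
    fill-to-finish throughput and bottleneck analysis, and capacity/resource
    projections for multi-billion-dose demand targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
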