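Package: androdyn
Title: Sex-Ratio Dynamics and Survival Statistics for Androdioecious Nematode Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studying how a male-secreted ascaroside
    pheromone culls males from androdioecious Caenorhabditis populations.
    Implements per-day progeny bookkeeping over the male mating window, the
    relative progeny factor r, the geometric male-frequency recursion
    m_X = m0 * r^X with its generations-to-hermaphroditism threshold, and a
    stochastic discrete-generation mating-system simulator, together with the
    supporting statistics: a Kaplan-Meier product-limit estimator, the
    log-rank (Mantel-Cox) test, mean-lifespan summaries and percent lifespan
    reduction, the chemotaxis index with t and permutation comparisons, and a
    hypergeometric gene-list overlap test. A seeded synthetic-data module
    generates survival cohorts (Gompertz hazards calibrated to target mean
    lifespans), per-day male fertility schedules, multinomial chemotaxis
    plates and offspring-sex draws under selfing versus outcrossing, so the
    full pipeline is testable without external data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
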