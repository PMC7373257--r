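Package: cafescore
Title: Polygenic Obesity Risk and Workplace Food-Purchase Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline from genotype dosages and cafeteria
    point-of-sale transaction logs to polygenic scores and purchase
    phenotypes: genotype quality control (exact Hardy-Weinberg test,
    call-rate and frequency filters, method-of-moments relatedness,
    ancestry principal components), polygenic risk scores with a
    CNS/non-CNS partition, a genome-wide polygenic score built by greedy
    LD clumping with a P-value threshold scan, traffic-light diet-quality
    scoring and meal-timing phenotypes from transaction logs, and
    quartile-based association models with trend, heterogeneity, and
    false-discovery-rate testing. Includes a synthetic-data generator
    with known generative parameters so the whole pipeline is testable
    without access to protected cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
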