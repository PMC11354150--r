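Package: raprs
Title: Case-Control SNP Association and Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for candidate-gene case-control association studies of
    rheumatoid arthritis and similar complex diseases: per-locus genotype and
    allele frequency summaries with chi-square and exact Hardy-Weinberg tests,
    crude and covariate-adjusted odds ratios under codominant, dominant,
    recessive and log-additive inheritance models, EM haplotype frequency
    estimation with pairwise linkage-disequilibrium statistics (D, D', r2),
    unweighted and odds-ratio-weighted polygenic risk scores with group
    comparisons, reconstruction of integer genotype counts from published
    rounded frequency tables, and a seeded synthetic-cohort generator for
    end-to-end testing without individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
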