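Package: mieo
Title: Factorial Screening and Minimum-Information Records for
    Engineered-Organism Growth Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and controlling the experimental factors
    that govern the growth and productivity of engineered microbes at bench
    scale. Constructs two-level full and fractional factorial screening
    designs with alias structure and centerpoint replicates; estimates factor
    effects with the relative effect magnitude statistic and normal-probability
    effect screening; quantifies repeatability and reproducibility of
    centerpoint replicates (within-day dispersion, between-month
    reproducibility, variance homogeneity, month variance fraction); computes
    phosphate-buffer media compositions from target pH and buffer capacity and
    culture-media osmolality with sodium chloride adjustment; converts raw
    plate-reader signals to dry cell mass, titer and yield through linear
    calibration curves; and reads, writes and validates nine-category
    Minimum Information for Engineered Organism Experiments (MIEO) v0.1
    records in tabular (CSV) and hierarchical (XML) dialects. A seeded
    synthetic-response generator emulates the statistical structure of a
    screening campaign so every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    yaml
Suggests:
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
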