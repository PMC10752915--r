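Package: plggtcf
Title: Tumor Cell Fraction Quantification and Culture Monitoring for
    Pediatric Low-Grade Glioma Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Droplet digital PCR (ddPCR) based quantification of tumor cell
    fraction (TCF) in primary pediatric low-grade glioma (pLGG) cultures, and
    longitudinal monitoring of culture composition during cell-line
    establishment. Converts raw droplet counts to target concentrations via
    the Poisson occupancy estimator, computes TCF from the BRAF exon-14
    duplication duplex and from the heterozygous BRAF V600E mutant/wild-type
    duplex with parametric-bootstrap confidence intervals, classifies culture
    trajectories (established vs failed), summarizes study cohorts, and
    provides a droplet-level synthetic data generator based on a growth
    competition (replicator) model of tumor versus microenvironmental cells.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
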