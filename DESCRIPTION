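Package: hdscan
Title: Genome-Wide Homozygosity Disequilibrium Scans for Treatment Response
Version: 0.1.0
Authors@R:
    person("GAW", "Analyst", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates per-individual homozygosity-intensity profiles from SNP
    genotypes with a double-weight local polynomial smoother over
    nearest-neighbor sliding windows, extracts runs-of-homozygosity regions,
    tests windows for association with a triglyceride response phenotype under
    generalized estimating equations with family clustering and sandwich
    covariance, corrects for correlated tests with an eigenvalue-based
    effective number of independent tests, and probes methylation regulation
    of homozygosity disequilibrium through beta-mixture quantile normalized
    cis/trans methylation-QTL scans. Includes a synthetic-data generator
    emulating a family-based pharmacogenomics cohort so the whole pipeline is
    testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Config/testthat/edition: 3
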