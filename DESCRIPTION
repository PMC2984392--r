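Package: poolmap
Title: Pooled-DNA SNP Microarray Allelotyping and Association Scans
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis toolkit for SNP Microarrays and Pooling
    (SNP-MaP) genome-wide association studies. Generates synthetic cohorts,
    stratified DNA pools and probe-level hybridization intensities under
    array designs with and without mismatch probes; computes relative allele
    signal (RAS) scores per pool and SNP; runs pool-level case-control scans
    with an independent Student's t-test, minor-allele-frequency exclusion
    and genome-wide significance flagging; and implements replicate
    correlation quality control, RAS-versus-true-frequency correlation
    stratified by DNA source, and the ratio-of-ratios concordance statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    digest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
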