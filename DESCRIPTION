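Package: mentropy
Title: Methylation Entropy and Spatial Correlation in Read-Level
    Bisulfite Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the read-level methylation pattern of an n-CpG segment
    as a correlated Bernoulli random vector constructed by thresholding a
    latent multivariate normal vector.  Computes the analytical relation
    between methylation entropy and methylation probability with and
    without spatial correlation between neighbouring CpG sites, provides a
    chi-square goodness-of-fit test for the existence (or a hypothesized
    structure) of spatial correlation, and implements a pipeline that
    extracts deeply covered CpG segments from per-read methylation calls
    and flags bipolar methylated loci, candidate markers of allele- or
    cell-type-specific methylation.  Includes seedable simulation engines
    for type-I error and power studies of the spatial test and for the
    empirical relation between observed methylation entropy and mean
    methylation level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    mvtnorm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
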