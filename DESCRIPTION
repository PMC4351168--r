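Package: chipconcord
Title: Positional Validation of SNP Array Membership Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits the array-availability claims of SNP annotation tools
    against the genotyping array's own product file. Membership of each
    query SNP is decided positionally (chromosome and 1-based GRCh37
    position against the manifest), tool claims are classified into true
    and false positives and negatives, and agreement is summarised with
    Cohen's kappa, false-negative and false-positive rates, and
    Landis-Koch verbal bands. Includes a seeded synthetic-data generator
    with known ground truth, a deterministic Cardio-Metabochip-shaped
    example fixture, and an enumeration routine that reconstructs 2x2
    table cells from published marginals and a printed kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
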