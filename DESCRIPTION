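Package: nagblup
Title: Genomic BLUP with Additive, Dominance and Epistatic Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct marker-based additive, dominance and
    additive-by-additive epistatic genomic relationship matrices from SNP
    genotypes, estimate the corresponding variance components by average
    information restricted maximum likelihood (AI-REML), predict genomic
    breeding values and total genetic values for unphenotyped individuals,
    and evaluate predictions for reliability and unbiasedness.  Includes a
    quantitative-genetics simulator (Hardy-Weinberg founders, Mendelian
    gamete sampling, full-sib litters) so the whole pipeline can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
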