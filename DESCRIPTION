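Package: biallele
Title: Genotype-Free Detection of Biallelic Transcript Expression from
    RNA-Seq Pileups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects biallelic expression of a transcript from per-position
    RNA-seq base counts when sample genotypes are unavailable, as arises when
    testing whether a normally silenced allele (for example the Y-linked copy
    of a pseudoautosomal-region gene such as SPRY3) has been reactivated.
    Provides a binomial genotype-likelihood classifier of per-site
    heterozygosity from reference-base fractions, sequencing-error calibration
    on hemizygous negative-control genes, per-sample heterozygosity maps with
    recurrent-artifact filtering, permutation and exact tests for cohort
    comparison of biallelic burden, a detection-power simulator, a samtools
    mpileup text reader, and a synthetic allelic-pileup generator that makes
    every stage testable without access to restricted data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
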