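Package: xcireact
Title: Allele-Specific Analysis of X-Chromosome Inactivation and Reactivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies expression from the active (Xa) and inactive (Xi) X
    chromosome using RNA-seq of reciprocal single-cell-derived female clones.
    Discovers heterozygous SNPs from per-position base-count pileups of the two
    clones, phases Xa/Xi alleles using the reciprocal-clone rule, aggregates
    allele-specific read counts per gene, fits a two-component beta-binomial
    mixture by EM to obtain a per-gene posterior probability of inactivation,
    and classifies genes as active, reactivated or inactive across a
    reprogramming time course. Includes a synthetic-data generator that
    produces reciprocal-clone pileups and time-course counts with known ground
    truth so every stage of the pipeline can be tested without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
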