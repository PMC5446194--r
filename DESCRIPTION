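Package: methocc
Title: Methylation Context, MeCP2 Occupancy and Transcriptional Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline linking DNA methylation context
    (mCG and non-CpG mCAC) to MeCP2 chromatin occupancy and to the direction
    of transcriptional mis-regulation. Provides strand-aware cytosine context
    classification and region methylation-density statistics, Input-corrected
    ChIP occupancy with a linear Input-predictability model and outlier
    partition, simplified summit calling with anchored meta-profiles,
    multiscale segmentation of occupancy into enriched and depleted domains,
    and size-factor normalised negative-binomial differential expression with
    a global library-scale correction. A fully specified synthetic-data
    generator with ground-truth records supports parameter-recovery and null
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
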