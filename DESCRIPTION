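Package: skimcnv
Title: Deletion and Duplication Discovery from Skim Sequencing of
    Mutagenized Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects large deletions and duplications in fast-neutron
    mutagenized plant populations from very low coverage ("skim")
    whole-genome sequencing and from SNP-array genotype calls. Read counts
    in fixed genomic windows are normalized per line, classified against
    cross-line depth statistics into homozygous-deletion, hemizygous-
    deletion and duplication candidates, and contiguous runs of candidate
    windows are scored with run-length statistics (the expected chance
    frequency of a run of n failed detections, F = p^n (1-p)^2). A parallel
    screen finds runs of null ("---") genotype calls in a marker matrix.
    Population-level summaries include the deletion size spectrum, unique
    deleted genome fraction, and the probability that a given locus is
    deleted somewhere in a population of mutant families. A synthetic-data
    generator simulates Poisson window counts over implanted truth sets so
    the whole pipeline is testable without sequencing data.
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
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    Rsamtools,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
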