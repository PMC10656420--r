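Package: parcensus
Title: Pseudoautosomal Boundary Detection and Sex-Chromosome Repeat Census
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Inference layer for locating pseudoautosomal boundaries (PAB)
    on mammalian sex chromosomes, censusing macrosatellite tandem repeats
    and ampliconic gene families, and demarcating inversions from synteny
    blocks. Boundaries are called both from X/Y homology transitions and
    from Poisson changepoints in male read depth; tandem-repeat monomers
    are inferred by k-mer recurrence periodicity, copies are enumerated and
    tiered by identity, and neighbor-joining trees relate repeat copies.
    Includes a deterministic synthetic sex-chromosome and long-read
    simulator with full ground truth, a built-in k-mer anchor-chaining
    aligner, and readers/writers for PAF and tabular BLAST alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    ape,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
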