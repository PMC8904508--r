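Package: adnapipe
Title: Ancient DNA Population Genetics: Pseudo-Haploid Calling,
    f-Statistics, qpAdm Modeling, Admixture Dating and Selection Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population-genetic inference from low-coverage
    ancient genomes: pseudo-haploid genotype calling from per-site read
    pileups with quality, end-trim and single-strand library rules;
    relatedness screening from pairwise mismatch rates; unbiased f2, f3
    and f4 statistics with weighted block-jackknife standard errors;
    qpWave rank tests and qpAdm admixture-weight estimation; least-squares
    admixture-graph fitting with greedy leaf addition; admixture dating
    from the exponential decay of ancestry covariance with genetic
    distance; a sliding-window outgroup-f3 selection scan with
    heterozygosity normalization and LD-block resampling z-scores; and
    Y-chromosome haplogroup assignment from branch-defining markers.
    A fully seeded synthetic-data generator (graph-drifted allele
    frequencies, pedigreed genotypes, damaged read pileups, admixed
    chromosomes with exponentially distributed ancestry tracts) provides
    ground truth for recovery tests. Reads and writes EIGENSTRAT, pileup
    TSV, BED and YAML formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    minpack.lm,
    pracma,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
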