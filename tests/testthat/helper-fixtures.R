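## Shared fixture builders for the test suite.  Everything is generated in
## code under fixed seeds; no data files.

## simple rooted tree: outgroup O at the root, A and B splitting from X
treeOAB <- function(cO = 0, cX = 0.02, cA = 0.01, cB = 0.01) {
  AdmixtureGraph(data.frame(
    parent = c("root", "root", "X", "X"),
    child = c("O", "X", "A", "B"),
    drift = c(cO, cX, cA, cB)))
}

## 8-population graph: 6 outgroup-like rights radiating from the root and
## a cladal pair (T1, T2) on a shared branch; the null for qpWave rank 0
cladalGraph <- function() {
  AdmixtureGraph(data.frame(
    parent = c(rep("root", 7), "P", "P"),
    child = c(paste0("R", 0:5), "P", "T1", "T2"),
    drift = c(0.05, 0.05, 0.06, 0.04, 0.05, 0.06, 0.03, 0.01, 0.01)))
}

## as above but T2 shares drift with the R5 lineage: not cladal with T1
nonCladalGraph <- function() {
  AdmixtureGraph(data.frame(
    parent = c("root", "root", "root", "root", "root", "root", "Q", "Q",
               "root", "P"),
    child = c("R0", "R1", "R2", "R3", "R4", "Q", "R5", "T2", "P", "T1"),
    drift = c(0.05, 0.05, 0.06, 0.04, 0.05, 0.03, 0.03, 0.02, 0.03, 0.01)))
}

## two-way admixture fixture for qpAdm: target T = alpha S1 + (1-alpha) S2
## relative to 6 rights with differential affinity to the source lineages
qpadmGraph <- function(alpha = 0.7) {
  e <- data.frame(
    parent = c("root", "root", "root", "root", "X", "X", "Y", "Y", "Z", "Z",
               "s1i", "s2i", "s1i", "s2i", "root"),
    child = c("R0", "R1", "R2", "X", "R3", "Y", "s1i", "Z", "R4", "s2i",
              "S1", "S2", "T", "T", "R5"),
    drift = c(0.05, 0.05, 0.05, 0.01, 0.04, 0.01, 0.01, 0.01, 0.04, 0.01,
              0.01, 0.01, 0.005, 0.005, 0.05))
  AdmixtureGraph(e, data.frame(child = "T", parentA = "s1i",
                               parentB = "s2i", alpha = alpha))
}

## identifiable 5-leaf graph with one admixed leaf (zero-length fixed legs)
admixedLeafGraph <- function(alpha = 0.4) {
  e <- data.frame(
    parent = c("root", "root", "X", "X", "Y", "Y", "Z", "W", "Z", "W"),
    child = c("O", "X", "A", "Y", "Z", "W", "B", "D", "C", "C"),
    drift = c(0.02, 0.02, 0.03, 0.01, 0.02, 0.02, 0.03, 0.03, 0, 0),
    fixed = c(rep(FALSE, 8), TRUE, TRUE))
  AdmixtureGraph(e, data.frame(child = "C", parentA = "Z", parentB = "W",
                               alpha = alpha))
}

## pseudo-haploid call matrix drawn directly from diploid genotypes
## (one uniformly sampled allele per site), bypassing the read layer
drawHaploid <- function(geno, seed) {
  m <- calls(geno)
  withSeed(adnapipe::subSeed(seed, "drawHaploid"), {
    h <- matrix(rbinom(length(m), 1, m / 2), nrow(m), ncol(m),
                dimnames = dimnames(m))
    CallMatrix(h, geno@panel, ploidy = 1L)
  })
}

## run under a temporary seed without disturbing the session RNG
withSeed <- adnapipe:::withSeed

## target/ancient/outgroup counts over a shared-history graph; optional
## frequency spike in the target inside a given physical window.  27
## diploid target and 103 diploid outgroup individuals, 18 pseudo-haploid
## ancient genomes with light missingness
scanFixture <- function(seed, spikeAt = NULL, spikeSize = 0.35,
                        nSnps = 42000) {
  panel <- simulatePanel(nSnps, nChrom = 2, chromLengthMb = 30,
                         seed = 400 + seed)
  g <- AdmixtureGraph(data.frame(
    parent = c("root", "root", "X", "X"),
    child = c("Han", "X", "Tib", "Anc"),
    drift = c(0.02, 0.01, 0.005, 0.005)))
  fr <- simulateFrequencies(g, panel, seed = 500 + seed)
  if (!is.null(spikeAt)) {
    s <- snpInfo(panel)
    hit <- s$chrom == spikeAt$chrom & s$pos >= spikeAt$from &
           s$pos < spikeAt$to
    fr@freq["Tib", hit] <- pmin(1, fr@freq["Tib", hit] + spikeSize)
  }
  ac <- bindCounts(
    sampleAlleleCounts(fr, c(Tib = 54), seed = seed),
    sampleAlleleCounts(fr, c(Han = 206), seed = 600 + seed),
    sampleAlleleCounts(fr, c(Anc = 18), ploidy = 1, missingRate = 0.05,
                       seed = 700 + seed))
  list(ac = ac, panel = panel)
}

## one hand-built pileup row
pileRow <- function(individual = "i1", chrom = "1", position = 100L,
                    base = "A", bq = 40L, mq = 60L, strand = "+",
                    rp = 30L, rl = 70L,
                    library = paste0(individual, "_L1"),
                    library_type = "double_strand") {
  data.frame(individual = individual, library = library, chrom = chrom,
             position = position, base = base, base_quality = bq,
             mapping_quality = mq, strand = strand, read_position = rp,
             read_length = rl, library_type = library_type,
             stringsAsFactors = FALSE)
}
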