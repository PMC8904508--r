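panelAG <- SNPPanel(chrom = "1", pos = c(100L, 200L, 300L),
                    ref = c("A", "C", "G"), alt = c("G", "T", "A"))

test_that("pseudo-haploid calling applies quality, trim and allele gates", {
  ## unanimous high-quality A reads at an A/G SNP: call 0 (reference)
  p <- rbind(pileRow(position = 100L, base = "A", bq = 37L),
             pileRow(position = 100L, base = "A", bq = 60L),
             pileRow(position = 100L, base = "A", bq = 60L))
  cm <- callPseudohaploid(p, panelAG, seed = 1)
  expect_identical(calls(cm)[1, "i1"], 0L)

  ## base quality below 30 at every read: missing
  pLow <- rbind(pileRow(position = 100L, base = "A", bq = 29L),
                pileRow(position = 100L, base = "G", bq = 20L))
  expect_true(is.na(calls(callPseudohaploid(pLow, panelAG, seed = 1))[1, 1]))

  ## mapping quality gate
  pMap <- pileRow(position = 100L, base = "A", mq = 29L)
  expect_true(is.na(calls(callPseudohaploid(pMap, panelAG, seed = 1))[1, 1]))

  ## a base at read position 3 of a 70 bp read falls in the 5 bp end trim
  pTrim <- pileRow(position = 100L, base = "A", rp = 3L, rl = 70L)
  expect_true(is.na(calls(callPseudohaploid(pTrim, panelAG, seed = 1))[1, 1]))
  ## ... and near the other end too
  pTrim2 <- pileRow(position = 100L, base = "A", rp = 67L, rl = 70L)
  expect_true(is.na(calls(callPseudohaploid(pTrim2, panelAG, seed = 1))[1, 1]))

  ## a base matching neither allele is ineligible, not an error
  pOther <- pileRow(position = 100L, base = "C")
  expect_true(is.na(calls(callPseudohaploid(pOther, panelAG, seed = 1))[1, 1]))

  ## unknown mode errors; positions off the panel are skipped with warning
  expect_error(callPseudohaploid(p, panelAG, mode = "triple"), "unknown mode")
  pOff <- rbind(p, pileRow(position = 999L, base = "A"))
  expect_warning(cm2 <- callPseudohaploid(pOff, panelAG, seed = 1), "skipped")
  expect_identical(attr(cm2, "skipped"), 1L)
})

test_that("single-strand mode keeps only the damage-safe strand", {
  ## C/T SNP: only minus-strand reads are eligible
  pCT <- rbind(pileRow(position = 200L, base = "C", strand = "+"),
               pileRow(position = 200L, base = "C", strand = "+"))
  expect_true(is.na(calls(callPseudohaploid(pCT, panelAG,
                                            mode = "single_strand",
                                            seed = 1))[2, 1]))
  pCTm <- pileRow(position = 200L, base = "C", strand = "-")
  expect_identical(calls(callPseudohaploid(pCTm, panelAG,
                                           mode = "single_strand",
                                           seed = 1))[2, "i1"], 0L)
  ## G/A SNP: only plus-strand reads
  pGA <- pileRow(position = 300L, base = "G", strand = "-")
  expect_true(is.na(calls(callPseudohaploid(pGA, panelAG,
                                            mode = "single_strand",
                                            seed = 1))[3, 1]))
})

test_that("calls are deterministic and invariant to pileup row order", {
  panel <- simulatePanel(3000, seed = 2)
  fr <- simulateFrequencies(treeOAB(), panel, seed = 3)
  co <- CohortSpec(c(A = 2), meanDepth = 3)
  geno <- simulateGenotypes(fr, co, seed = 4)
  pile <- simulatePileup(geno, co, panel, seed = 5)
  c1 <- callPseudohaploid(pile, panel, seed = 9)
  c2 <- callPseudohaploid(pile[sample.int(nrow(pile)), ], panel, seed = 9)
  expect_identical(calls(c1), calls(c2))
  ## and stable under subsetting to half the panel
  half <- panel[seq_len(1500)]
  cHalf <- suppressWarnings(callPseudohaploid(pile, half, seed = 9))
  expect_identical(calls(cHalf)[, "A_1"], calls(c1)[seq_len(1500), "A_1"])
})

test_that("undamaged unanimous pileups always call a true allele", {
  panel <- simulatePanel(2000, seed = 6)
  fr <- simulateFrequencies(treeOAB(), panel, seed = 7)
  co <- CohortSpec(c(A = 2), meanDepth = 2, damageRate = 0)
  geno <- simulateGenotypes(fr, co, seed = 8)
  pile <- simulatePileup(geno, co, panel, seed = 9)
  cm <- callPseudohaploid(pile, panel, seed = 10)
  m <- calls(cm); gm <- calls(geno)
  for (ind in colnames(m)) {
    called <- !is.na(m[, ind])
    ## a haploid call of x requires genotype dosage compatible with x
    expect_true(all(gm[called, ind] >= m[called, ind]))
    expect_true(all((2 - gm[called, ind]) >= (1 - m[called, ind])))
  }
})

test_that("EIGENSTRAT trios round-trip losslessly", {
  panel <- simulatePanel(60, seed = 11)
  m <- matrix(sample(c(0L, 1L, NA), 120, TRUE), 60, 2,
              dimnames = list(snpInfo(panel)$id, c("i1", "i2")))
  cm <- CallMatrix(m, panel, ploidy = 1)
  pre <- file.path(tempdir(), "rt")
  writeEigenstrat(cm, pre)
  rt <- readEigenstrat(pre, ploidy = 1)
  expect_identical(calls(rt$calls), calls(cm))
  expect_equal(snpInfo(rt$panel)$pos, snpInfo(panel)$pos)
  expect_equal(snpInfo(rt$panel)$gpos, snpInfo(panel)$gpos, tolerance = 1e-9)

  ## diploid round-trip with missing as 9
  md <- matrix(sample(c(0:2, NA), 120, TRUE), 60, 2,
               dimnames = list(snpInfo(panel)$id, c("i1", "i2")))
  writeEigenstrat(CallMatrix(md, panel, ploidy = 2), pre)
  expect_identical(calls(readEigenstrat(pre, ploidy = 2)$calls), md)
})

test_that("a hand-written EIGENSTRAT fixture parses to the expected matrix", {
  pre <- file.path(tempdir(), "toy")
  ## .geno values count REFERENCE alleles; 9 is missing
  writeLines(c("02", "19", "20"), paste0(pre, ".geno"))
  writeLines(c("rs1  1  0.0010  100 A G",
               "rs2  1  0.0020  200 C T",
               "rs3  1  0.0030  300 G A"), paste0(pre, ".snp"))
  writeLines(c("s1 U Pop1", "s2 U Pop2"), paste0(pre, ".ind"))
  es <- readEigenstrat(pre, ploidy = 2)
  expect_identical(calls(es$calls),
                   matrix(c(2L, 1L, 0L, 0L, NA, 2L), 3, 2,
                          dimnames = list(snpInfo(es$panel)$id, c("s1", "s2"))))
  expect_identical(es$ind$group, c("Pop1", "Pop2"))
  ## ragged line reported with its number
  writeLines(c("02", "1", "20"), paste0(pre, ".geno"))
  expect_error(readEigenstrat(pre), "line 2")
})

test_that("panel merging intersects, drops ambiguous sites and flips swaps", {
  panel <- SNPPanel(chrom = "1", pos = c(10L, 20L, 30L, 40L),
                    ref = c("A", "A", "C", "G"), alt = c("G", "T", "T", "C"))
  m <- matrix(c(0L, 1L, 0L, 1L, 1L, NA, 0L, 0L), 4, 2,
              dimnames = list(snpInfo(panel)$id, c("x", "y")))
  cm <- CallMatrix(m, panel, ploidy = 1)
  self <- mergePanels(list(a = cm, b = cm))
  ## A/T at pos 20 and C/G at pos 40 are strand-ambiguous
  expect_identical(self$log$strand_ambiguous_removed, 2L)
  expect_identical(nSnps(self$panel), 2L)
  expect_identical(calls(self$datasets$a), calls(self$datasets$b))

  keepAll <- mergePanels(list(a = cm, b = cm), dropStrandAmbiguous = FALSE)
  expect_identical(nSnps(keepAll$panel), 4L)

  ## ref/alt swapped second dataset harmonizes by flipping dosage
  p2 <- SNPPanel(chrom = "1", pos = c(10L, 20L, 30L, 40L),
                 ref = c("G", "A", "T", "G"), alt = c("A", "T", "C", "C"))
  m2 <- m; m2[c(1, 3), ] <- 1L - m2[c(1, 3), ]
  cm2 <- CallMatrix(m2, p2, ploidy = 1)
  mg <- mergePanels(list(a = cm, b = cm2))
  expect_identical(calls(mg$datasets$a), calls(mg$datasets$b))

  ## irreconcilable alleles are dropped and counted
  p3 <- SNPPanel(chrom = "1", pos = c(10L, 20L, 30L, 40L),
                 ref = c("A", "A", "C", "G"), alt = c("C", "T", "T", "C"))
  cm3 <- CallMatrix(m, p3, ploidy = 1)
  mg3 <- mergePanels(list(a = cm, b = cm3))
  expect_identical(mg3$log$irreconcilable_dropped, 1L)
  expect_identical(nSnps(mg3$panel), 1L)
})

test_that("pileup TSV round-trips through the validator", {
  p <- rbind(pileRow(), pileRow(position = 200L, base = "C", strand = "-"))
  f <- file.path(tempdir(), "pile.tsv")
  writePileupTable(p, f)
  expect_identical(readPileupTable(f), p)
  bad <- p; bad$base[1] <- "N"
  expect_error(validatePileup(bad))
})
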