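test_that("graph validity catches cycles, multiple roots and bad parameters", {
  expect_error(AdmixtureGraph(data.frame(parent = c("a", "b"),
                                         child = c("b", "a"),
                                         drift = c(0.1, 0.1))),
               "cycle|root")
  expect_error(AdmixtureGraph(data.frame(parent = c("r", "s"),
                                         child = c("a", "b"),
                                         drift = c(0.1, 0.1))),
               "root")
  expect_error(AdmixtureGraph(data.frame(parent = "r", child = "a",
                                         drift = -0.1)), ">= 0")
  expect_error(
    AdmixtureGraph(data.frame(parent = c("r", "r", "a", "b"),
                              child = c("a", "b", "m", "m"),
                              drift = 0.1),
                   data.frame(child = "m", parentA = "a", parentB = "b",
                              alpha = 1.5)),
    "\\[0, 1\\]")
})

test_that("zero drift propagates the root frequency unchanged", {
  panel <- simulatePanel(500, seed = 1)
  fr <- simulateFrequencies(treeOAB(0, 0, 0, 0), panel, seed = 2)
  f <- freq(fr)
  expect_identical(f["O", ], f["A", ])
  expect_identical(f["A", ], f["B", ])
})

test_that("an admixture node mixes its parents as a convex combination", {
  ## no drift on the admixture legs: child must equal alpha*pA + (1-alpha)*pB
  g <- AdmixtureGraph(
    data.frame(parent = c("root", "root", "PA", "PB"),
               child = c("PA", "PB", "M", "M"),
               drift = c(0.05, 0.05, 0, 0)),
    data.frame(child = "M", parentA = "PA", parentB = "PB", alpha = 0.3))
  panel <- simulatePanel(400, seed = 3)
  f <- freq(simulateFrequencies(g, panel, seed = 4))
  expect_equal(f["M", ], 0.3 * f["PA", ] + 0.7 * f["PB", ], tolerance = 1e-12)
})

test_that("drift variance matches the closed-form expectation", {
  ## E[(o-a)(o-b)] = c_shared * E[p(1-p)]; Beta(0.46, 0.46) gives
  ## E[p(1-p)] = ab/((a+b)(a+b+1)) ~= 0.11979
  panel <- simulatePanel(100000, seed = 5)
  f <- freq(simulateFrequencies(treeOAB(), panel, seed = 6))
  v <- (f["O", ] - f["A", ]) * (f["O", ] - f["B", ])
  expected <- 0.02 * (0.46^2 / (0.92 * 1.92))
  mcse <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - expected), 3 * mcse)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("frequency draws are reproducible and boundary hits are counted", {
  panel <- simulatePanel(2000, seed = 7)
  a <- simulateFrequencies(treeOAB(), panel, seed = 8)
  b <- simulateFrequencies(treeOAB(), panel, seed = 8)
  expect_identical(freq(a), freq(b))
  ## drift >= 1 exceeds the Beta-feasible variance: every draw truncates
  big <- simulateFrequencies(
    AdmixtureGraph(data.frame(parent = "root", child = "A", drift = 1.5)),
    panel, seed = 9)
  expect_true(all(freq(big)["A", ] %in% c(0, 1)))
  expect_gt(big@clipped, 0)
})

test_that("genotypes follow Hardy-Weinberg and Mendelian transmission", {
  panel <- simulatePanel(50000, seed = 10)
  fr <- simulateFrequencies(
    AdmixtureGraph(data.frame(parent = "root", child = "A", drift = 0)),
    panel, seed = 11)
  ped <- data.frame(indA = c("A_1", "A_3", "A_5"),
                    indB = c("A_2", "A_4", "A_6"),
                    relation = c("duplicate", "parent_offspring",
                                 "second_degree"))
  co <- CohortSpec(c(A = 6), pedigree = ped)
  geno <- simulateGenotypes(fr, co, seed = 12)
  m <- calls(geno)
  ## expected heterozygosity under Beta(0.46, 0.46): a/(2a+1) ~= 0.2396
  expect_equal(mean(m[, "A_1"] == 1), 0.46 / 1.92, tolerance = 0.02)
  expect_identical(m[, "A_1"], m[, "A_2"])
  ## parent-offspring share an allele at every SNP
  incompatible <- (m[, "A_3"] == 0 & m[, "A_4"] == 2) |
                  (m[, "A_3"] == 2 & m[, "A_4"] == 0)
  expect_false(any(incompatible))
  expect_error(simulateGenotypes(fr, CohortSpec(c(Zz = 2)), seed = 1),
               "unknown group")
})

test_that("monomorphic sites yield monomorphic genotypes", {
  panel <- simulatePanel(100, seed = 13)
  fr <- simulateFrequencies(
    AdmixtureGraph(data.frame(parent = "root", child = "A", drift = 0)),
    panel, seed = 14)
  fr@freq[] <- 0
  geno <- simulateGenotypes(fr, CohortSpec(c(A = 4)), seed = 15)
  expect_true(all(calls(geno) == 0))
})

test_that("pileup respects depth, alleles and the deamination model", {
  panel <- simulatePanel(4000, seed = 16, alleles = c("C", "T"))
  fr <- simulateFrequencies(
    AdmixtureGraph(data.frame(parent = "root", child = "A", drift = 0)),
    panel, seed = 17)
  co0 <- CohortSpec(c(A = 1), meanDepth = 0)
  geno0 <- simulateGenotypes(fr, co0, seed = 18)
  expect_identical(nrow(simulatePileup(geno0, co0, panel, seed = 19)), 0L)

  ## delta = 0: every read base is a true allele of the individual
  co <- CohortSpec(c(A = 2), meanDepth = 2, damageRate = 0)
  geno <- simulateGenotypes(fr, co, seed = 20)
  pile <- simulatePileup(geno, co, panel, seed = 21)
  s <- snpInfo(panel)
  key <- match(paste(pile$chrom, pile$position), paste(s$chrom, s$pos))
  gdos <- calls(geno)[cbind(key, match(pile$individual, colnames(calls(geno))))]
  okRef <- pile$base == s$ref[key] & gdos < 2
  okAlt <- pile$base == s$alt[key] & gdos > 0
  expect_true(all(okRef | okAlt))

  ## delta = 0.1 on C/C genotypes: T appears on terminal plus-strand reads
  ## at close to the damage rate, and never on minus-strand reads
  frCC <- fr; frCC@freq[] <- 0
  coD <- CohortSpec(c(A = 3), meanDepth = 8, damageRate = 0.1)
  genoCC <- simulateGenotypes(frCC, coD, seed = 22)
  pd <- simulatePileup(genoCC, coD, panel, seed = 23)
  term <- pd$read_position <= 5 | pd$read_position > pd$read_length - 5
  plusT <- mean(pd$base[term & pd$strand == "+"] == "T")
  minusT <- mean(pd$base[term & pd$strand == "-"] == "T")
  expect_equal(plusT, 0.1, tolerance = 0.015)
  expect_identical(minusT, 0)
  expect_error(simulatePileup(genoCC, coD, panel, readLen = 8, seed = 1),
               "exceed 10")
})

test_that("admixed chromosomes have exponential tracts at the Markov rate", {
  panel <- simulatePanel(6000, nChrom = 5, chromLengthMb = 100, seed = 24)
  fr <- simulateFrequencies(
    AdmixtureGraph(data.frame(parent = c("root", "root"),
                              child = c("P1", "P2"), drift = c(0.1, 0.1))),
    panel, seed = 25)
  sim <- simulateAdmixedGenotypes(fr, "P1", "P2", alpha = 0.5, g = 46,
                                  nInd = 25, seed = 26)
  tr1 <- sim$tracts[sim$tracts$state == "P1", ]
  ## sojourn time of the source-1 state: 1 / ((1 - alpha) g) Morgans
  expect_equal(mean(tr1$end - tr1$start), 1 / (0.5 * 46), tolerance = 0.1)
  sim2 <- simulateAdmixedGenotypes(fr, "P1", "P2", alpha = 0.5, g = 92,
                                   nInd = 25, seed = 27)
  tr2 <- sim2$tracts[sim2$tracts$state == "P1", ]
  expect_equal(mean(tr1$end - tr1$start) / mean(tr2$end - tr2$start), 2,
               tolerance = 0.15)
  ## alpha = 1: everything from source 1
  all1 <- simulateAdmixedGenotypes(fr, "P1", "P2", alpha = 1, g = 46,
                                   nInd = 2, seed = 28)
  expect_true(all(all1$tracts$state == "P1"))
  expect_true(all(all1$ancestry == 2L))
  expect_error(simulateAdmixedGenotypes(fr, "P1", "P2", 0.5, g = 0,
                                        nInd = 1, seed = 1), "> 0")
  ## bit-identical reruns under the same seed
  rerun <- simulateAdmixedGenotypes(fr, "P1", "P2", alpha = 0.5, g = 46,
                                    nInd = 25, seed = 26)
  expect_identical(calls(rerun$calls), calls(sim$calls))
  expect_identical(rerun$tracts, sim$tracts)
})

test_that("empirical f2 between leaves matches the drift path length", {
  panel <- simulatePanel(100000, seed = 29)
  f <- freq(simulateFrequencies(treeOAB(), panel, seed = 30))
  v <- (f["A", ] - f["B", ])^2
  ## E[p(1-p)] shrinks by (1 - c) along each edge: the A-B path sees the
  ## heterozygosity at X, i.e. root * (1 - cX)
  hetRoot <- 0.46^2 / (0.92 * 1.92)
  expected <- (0.01 + 0.01) * hetRoot * (1 - 0.02)
  expect_lt(abs(mean(v) - expected), 3 * sd(v) / sqrt(length(v)))
})
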