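## allele-count fixture over a small drifted graph
mkAc <- function(nSnps = 20000, seed = 1, sizes = c(O = 20, A = 20, B = 20)) {
  panel <- simulatePanel(nSnps, nChrom = 4, chromLengthMb = 50,
                         seed = seed)
  fr <- simulateFrequencies(treeOAB(), panel, seed = seed + 1)
  list(ac = sampleAlleleCounts(fr, sizes, seed = seed + 2),
       panel = panel, fr = fr, blocks = assignBlocks(panel))
}

test_that("f2 vanishes on identical counts and saturates at fixation", {
  panel <- simulatePanel(100, seed = 3)
  x <- matrix(rep(c(5, 5), each = 100), 2, 100, byrow = TRUE,
              dimnames = list(c("A", "B"), NULL))
  n <- matrix(10, 2, 100, dimnames = dimnames(x))
  ac <- new("AlleleCounts", x = x, n = n,
            ploidy = c(A = 2L, B = 2L), panel = panel)
  expect_identical(f2(ac, "A", "B", corrected = FALSE)@estimate, 0)
  xf <- x; xf["A", ] <- 1000; xf["B", ] <- 0
  nf <- n; nf[] <- 1000
  acf <- new("AlleleCounts", x = xf, n = nf,
             ploidy = c(A = 2L, B = 2L), panel = panel)
  expect_equal(f2(acf, "A", "B", corrected = FALSE)@estimate, 1)
  expect_equal(f2(acf, "A", "B", corrected = TRUE)@estimate, 1)
})

test_that("f4 is antisymmetric and vanishes on a repeated pair", {
  fx <- mkAc(5000, seed = 5)
  expect_identical(f4(fx$ac, "A", "B", "O", "O")@estimate, 0)
  a1 <- f4(fx$ac, "A", "B", "O", "A")@estimate
  a2 <- f4(fx$ac, "B", "A", "O", "A")@estimate
  expect_equal(a1, -a2, tolerance = 1e-15)
  ## f4(A,B;A,B) equals uncorrected f2(A,B) as an identity
  expect_equal(f4(fx$ac, "A", "B", "A", "B")@estimate,
               f2(fx$ac, "A", "B", corrected = FALSE)@estimate,
               tolerance = 1e-15)
})

test_that("blocked aggregates equal a naive per-SNP loop to 1e-12", {
  fx <- mkAc(8000, seed = 7)
  ## independent brute-force recomputation from raw counts
  x <- fx$ac@x; n <- fx$ac@n
  naive <- 0; used <- 0
  for (k in seq_len(ncol(x))) {
    a <- x["A", k] / n["A", k]; b <- x["B", k] / n["B", k]
    o <- x["O", k] / n["O", k]
    naive <- naive + (a - b) * (o - a)
    used <- used + 1
  }
  r <- f4(fx$ac, "A", "B", "O", "A", blocks = fx$blocks)
  expect_lt(abs(r@estimate - naive / used), 1e-12)
  expect_identical(r@nSnps, as.integer(used))
  ## estimate is invariant to SNP order / block relabeling
  perm <- sample(seq_len(nSnps(fx$panel)))
  ac2 <- new("AlleleCounts", x = x[, perm], n = n[, perm],
             ploidy = fx$ac@ploidy, panel = fx$panel)
  r2 <- f4(ac2, "A", "B", "O", "A", blocks = fx$blocks[perm])
  expect_equal(r2@estimate, r@estimate, tolerance = 1e-15)
  expect_equal(r2@se, r@se, tolerance = 1e-12)
})

test_that("f3 recovers the shared drift of the generator", {
  fx <- mkAc(100000, seed = 9, sizes = c(O = 40, A = 40, B = 40))
  d <- f3(fx$ac, "O", "A", "B", blocks = fx$blocks, details = TRUE)
  expected <- 0.02 * 0.46^2 / (0.92 * 1.92)
  mcse <- sd(d$perSnp[d$use]) / sqrt(sum(d$use))
  expect_lt(abs(d$result@estimate - expected), 3 * mcse)
})

test_that("outgroup-f3 ranks the sister population highest", {
  ## four leaves: B is the sister of A; f3(O; A, .) peaks at B
  g <- AdmixtureGraph(data.frame(
    parent = c("root", "root", "X", "X", "Y", "Y"),
    child = c("O", "X", "C", "Y", "A", "B"),
    drift = c(0, 0.02, 0.01, 0.015, 0.01, 0.01)))
  panel <- simulatePanel(30000, seed = 11)
  fr <- simulateFrequencies(g, panel, seed = 12)
  ac <- sampleAlleleCounts(fr, c(O = 20, A = 20, B = 20, C = 20), seed = 13)
  vals <- vapply(c("B", "C"), function(y)
    f3(ac, "O", "A", y)@estimate, numeric(1))
  expect_identical(names(which.max(vals)), "B")
})

test_that("the f3 correction is refused for pseudo-haploid targets", {
  fx <- mkAc(2000, seed = 15)
  fx$ac@ploidy["O"] <- 1L
  expect_message(f3(fx$ac, "O", "A", "B"), "pseudo-haploid")
})

test_that("block jackknife matches brute-force delete-one at equal weights", {
  withSeed(17, {
    v <- rnorm(300)
    b <- rep(1:30, each = 10)
    jk <- blockJackknife(v, b)
    loo <- vapply(1:30, function(j) mean(v[b != j]), numeric(1))
    expect_equal(jk$loo, loo, tolerance = 1e-12)
    B <- 30
    se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
    expect_equal(jk$se, se, tolerance = 1e-12)
    expect_equal(jk$estimate, mean(v), tolerance = 1e-15)
  })
  ## identical block values: SE exactly 0
  expect_equal(blockJackknife(rep(2, 100), rep(1:10, each = 10))$se, 0)
  expect_error(blockJackknife(1:5, rep(1, 5)), "2 non-empty blocks")
})

test_that("jackknife SEs track the sampling SD of the estimator", {
  panel <- simulatePanel(10000, nChrom = 5, chromLengthMb = 40, seed = 19)
  blocks <- assignBlocks(panel)
  ests <- ses <- numeric(60)
  for (i in seq_along(ests)) {
    fr <- simulateFrequencies(treeOAB(), panel, seed = 500 + i)
    ac <- sampleAlleleCounts(fr, c(O = 20, A = 20, B = 20), seed = i)
    r <- f3(ac, "O", "A", "B", blocks = blocks)
    ests[i] <- r@estimate; ses[i] <- r@se
  }
  expect_lt(abs(mean(ses) - sd(ests)) / sd(ests), 0.25)
})

test_that("corrected statistics are unbiased for the true-frequency value", {
  ## uncorrected f2 on true frequencies vs corrected f2 on sampled counts
  panel <- simulatePanel(50000, seed = 21)
  fr <- simulateFrequencies(treeOAB(), panel, seed = 22)
  f <- freq(fr)
  truth <- mean((f["A", ] - f["B", ])^2)
  ac <- sampleAlleleCounts(fr, c(A = 10, B = 10), seed = 23)
  d <- f2(ac, "A", "B", corrected = TRUE, details = TRUE)
  mcse <- sd(d$perSnp[d$use]) / sqrt(sum(d$use))
  expect_lt(abs(d$result@estimate - truth), 3 * mcse)
  ## the uncorrected version is visibly biased upward
  expect_gt(f2(ac, "A", "B", corrected = FALSE)@estimate, truth + 3 * mcse)
})

test_that("weighted aggregation matches the mean under uniform coverage", {
  fx <- mkAc(3000, seed = 27)
  m1 <- f2(fx$ac, "A", "B", blocks = fx$blocks)
  m2 <- f2(fx$ac, "A", "B", blocks = fx$blocks, aggregation = "weighted")
  ## constant n per SNP: identical estimates and SEs
  expect_equal(m2@estimate, m1@estimate, tolerance = 1e-14)
  expect_equal(m2@se, m1@se, tolerance = 1e-12)
  ## heterogeneous coverage: low-coverage SNPs are down-weighted
  fx$ac@n["A", 1:1500] <- 2
  fx$ac@x["A", 1:1500] <- pmin(fx$ac@x["A", 1:1500], 2)
  w1 <- f2(fx$ac, "A", "B", blocks = fx$blocks)
  w2 <- f2(fx$ac, "A", "B", blocks = fx$blocks, aggregation = "weighted")
  expect_false(isTRUE(all.equal(w1@estimate, w2@estimate)))
})

test_that("missing populations at a SNP drop it from the statistic", {
  fx <- mkAc(1000, seed = 25)
  fx$ac@n["A", 1:100] <- 0
  fx$ac@x["A", 1:100] <- 0
  r <- f2(fx$ac, "A", "B", corrected = FALSE)
  expect_identical(r@nSnps, 900L)
  fx$ac@n["A", ] <- 0; fx$ac@x["A", ] <- 0
  expect_error(f2(fx$ac, "A", "B"), "no overlapping SNPs")
})
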