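rightsSix <- paste0("R", 0:5)

## counts fixture on the qpAdm graph
qpadmCounts <- function(seed, alpha = 0.7, nSnps = 30000, size = 20) {
  panel <- simulatePanel(nSnps, nChrom = 10, chromLengthMb = 50,
                         seed = 1000 + seed)
  fr <- simulateFrequencies(qpadmGraph(alpha), panel, seed = 2000 + seed)
  pops <- c(rightsSix, "S1", "S2", "T")
  list(ac = sampleAlleleCounts(fr, setNames(rep(size, length(pops)), pops),
                               seed = seed),
       blocks = assignBlocks(panel))
}

test_that("the f4 matrix is consistent with the fstats module", {
  fx <- qpadmCounts(seed = 1, nSnps = 10000)
  f4m <- buildF4Matrix(fx$ac, c("T", "S1", "S2"), rightsSix, fx$blocks)
  for (i in c("S1", "S2")) for (j in paste0("R", 1:5)) {
    direct <- f4(fx$ac, "T", i, "R0", j, blocks = fx$blocks)
    expect_equal(f4m$X[i, j], direct@estimate, tolerance = 1e-12)
  }
  ## duplicated left population gives a row of (near-)zeros
  f4d <- buildF4Matrix(fx$ac, c("T", "T", "S1"), rightsSix, fx$blocks)
  expect_identical(unname(f4d$X["T", ]), rep(0, 5))
  expect_error(buildF4Matrix(fx$ac, c("T", "S1"), c("R0", "R1"), fx$blocks),
               "at least 2 right")
  expect_error(buildF4Matrix(fx$ac, c("T", "R0"), rightsSix, fx$blocks),
               "disjoint")
})

test_that("allsnps uses per-entry SNP sets where the intersection is empty", {
  fx <- qpadmCounts(seed = 2, nSnps = 6000)
  ## knock out S1 on the first half and S2 on the second: no global overlap
  half <- seq_len(3000)
  fx$ac@n["S1", half] <- 0; fx$ac@x["S1", half] <- 0
  fx$ac@n["S2", -half] <- 0; fx$ac@x["S2", -half] <- 0
  expect_error(buildF4Matrix(fx$ac, c("T", "S1", "S2"), rightsSix,
                             fx$blocks, allsnps = FALSE),
               "no SNPs covered")
  f4m <- buildF4Matrix(fx$ac, c("T", "S1", "S2"), rightsSix, fx$blocks,
                       allsnps = TRUE)
  expect_true(all(is.finite(f4m$est)))
})

test_that("a zero f4 matrix passes every rank test with p = 1", {
  X <- matrix(0, 2, 5)
  Q <- diag(10)
  out <- qpWaveTest(X, Q = Q)
  expect_identical(out$statistic, rep(0, 2))
  expect_identical(out$p, rep(1, 2))
  expect_identical(out$df, c(10L, 4L))
})

test_that("qpAdm recovers the simulated mixture proportion", {
  fx <- qpadmCounts(seed = 3, alpha = 0.7)
  fit <- qpAdm(fx$ac, "T", c("S1", "S2"), rightsSix, fx$blocks)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_lt(abs(fit$weights[["S1"]] - 0.7), 3 * fit$se[["S1"]])
  expect_true(fit$feasible)
  expect_gt(fit$p, 0.001)
  ## a target identical to a source: weight ~ (1, 0)
  fitT <- qpAdm(fx$ac, "S1",
                c("S2", "T"), rightsSix, fx$blocks)
  expect_gt(fitT$weights[["T"]], 0.8)
  ## duplicated sources are collinear
  expect_error(qpAdm(fx$ac, "T", c("S1", "S1"), rightsSix, fx$blocks),
               "collinear")
})

test_that("qpAdm weights are invariant to source order up to permutation", {
  fx <- qpadmCounts(seed = 4, nSnps = 15000)
  f1 <- qpAdm(fx$ac, "T", c("S1", "S2"), rightsSix, fx$blocks)
  f2 <- qpAdm(fx$ac, "T", c("S2", "S1"), rightsSix, fx$blocks)
  expect_equal(f1$weights[["S1"]], f2$weights[["S1"]], tolerance = 1e-8)
  expect_equal(f1$p, f2$p, tolerance = 1e-8)
})

test_that("an impossible mixture is reported infeasible, not clamped", {
  ## target = S1 modeled from {even mixture of S1/S2, S2}: the solution
  ## is w = (2, -1), outside [0, 1]
  panel <- simulatePanel(30000, nChrom = 10, chromLengthMb = 50, seed = 91)
  fr <- simulateFrequencies(qpadmGraph(0.5), panel, seed = 92)
  pops <- c(rightsSix, "S1", "S2", "T")
  ac <- sampleAlleleCounts(fr, setNames(rep(30, length(pops)), pops),
                           seed = 93)
  blocks <- assignBlocks(panel)
  fit <- qpAdm(ac, "S1", c("T", "S2"), rightsSix, blocks)
  expect_false(fit$feasible)
  expect_gt(fit$weights[["T"]], 1)
  expect_lt(fit$weights[["S2"]], 0)
})

test_that("undifferentiating rights trigger the SE blow-up diagnostic", {
  ## rights all split off at the root carry no information about which
  ## source the target resembles when sources are nearly identical
  e <- data.frame(
    parent = c(rep("root", 7), "P", "P", "s1", "s2"),
    child = c(rightsSix, "P", "s1", "s2", "S1", "S2"),
    drift = c(rep(0.05, 6), 0.03, 1e-4, 1e-4, 1e-4, 1e-4))
  g <- AdmixtureGraph(e)
  panel <- simulatePanel(5000, nChrom = 10, chromLengthMb = 50, seed = 94)
  fr <- simulateFrequencies(g, panel, seed = 95)
  ac <- sampleAlleleCounts(fr, setNames(rep(10, 8), c(rightsSix, "S1", "S2")),
                           seed = 96)
  ## model S2 from (S1, R0): sources barely separable from the rights
  fit <- tryCatch(qpAdm(ac, "S2", c("S1", "R0"), rightsSix[-1],
                        assignBlocks(panel)),
                  error = function(err) err)
  ok <- inherits(fit, "error") ||
        isTRUE(fit$diagnostics$se_blowup) || any(fit$se > 0.5)
  expect_true(ok)
})

test_that("greedy candidate enumeration covers single edges and pairs", {
  base <- treeOAB()
  fx <- qpadmCounts(seed = 5, nSnps = 4000)
  ## rename pops so the base leaves exist: reuse tree fixture counts
  panel <- simulatePanel(6000, nChrom = 8, chromLengthMb = 50, seed = 97)
  fr <- simulateFrequencies(
    AdmixtureGraph(data.frame(parent = c("root", "root", "X", "X", "A"),
                              child = c("O", "X", "A", "B", "E"),
                              drift = c(0.01, 0.02, 0.01, 0.01, 0.01))),
    panel, seed = 98)
  ac <- sampleAlleleCounts(fr, c(O = 20, A = 20, B = 20, E = 20), seed = 99)
  blocks <- assignBlocks(panel)
  cands <- greedyAddLeaf(base, "E", ac, blocks, nStarts = 1, seed = 1)
  E <- nrow(graphEdges(base))
  expect_length(cands, E + E * (E - 1) / 2)
  expect_identical(cands[[1]]$attachment, "edge X->A")
})

test_that("an added twin leaf attaches at its twin with near-zero drift", {
  panel <- simulatePanel(8000, nChrom = 8, chromLengthMb = 50, seed = 101)
  g <- AdmixtureGraph(data.frame(parent = c("root", "root", "X", "X", "B"),
                                 child = c("O", "X", "A", "B", "B2"),
                                 drift = c(0.01, 0.02, 0.02, 0.02, 1e-5)))
  fr <- simulateFrequencies(g, panel, seed = 102)
  ac <- sampleAlleleCounts(fr, c(O = 40, A = 40, B = 40, B2 = 40), seed = 103)
  blocks <- assignBlocks(panel)
  cands <- greedyAddLeaf(treeOAB(), "B2", ac, blocks, nStarts = 1, seed = 1)
  best <- cands[[1]]
  expect_identical(best$attachment, "edge X->B")
  newEdge <- best$fit$graph@edges
  leafDrift <- newEdge$drift[newEdge$child == "B2"]
  expect_lt(leafDrift, 0.002)
})

test_that("the greedy search is order-dependent on an admixed fixture", {
  ## truth: P is an even mixture of the A- and B-side lineages and E is a
  ## sister of A; inserting (P then E) vs (E then P) yields different
  ## placements of P's A-side parent relative to E's junction
  gTrue <- AdmixtureGraph(data.frame(
    parent = c("root", "root", "X", "X", "Aa", "Aa", "Bb", "Aa2", "Bb2",
               "Aa2", "Bb2", "M"),
    child = c("O", "X", "Aa", "Bb", "E", "Aa2", "Bb2", "A", "B", "M", "M",
              "P"),
    drift = c(0.02, 0.02, 0.01, 0.02, 0.02, 0.01, 0.01, 0.015, 0.015, 0, 0,
              0.01)),
    data.frame(child = "M", parentA = "Aa2", parentB = "Bb2", alpha = 0.5))
  panel <- simulatePanel(12000, nChrom = 10, chromLengthMb = 50, seed = 104)
  blocks <- assignBlocks(panel)
  fr <- simulateFrequencies(gTrue, panel, seed = 105)
  ac <- sampleAlleleCounts(fr, setNames(rep(30, 5), c("O", "A", "B", "E", "P")),
                           seed = 106)
  base <- AdmixtureGraph(data.frame(parent = c("root", "root", "X", "X"),
                                    child = c("O", "X", "A", "B"),
                                    drift = c(0.02, 0.02, 0.03, 0.03)))
  addTwo <- function(first, second) {
    c1 <- greedyAddLeaf(base, first, ac, blocks, nStarts = 1, seed = 1)
    greedyAddLeaf(c1[[1]]$fit$graph, second, ac, blocks, nStarts = 1,
                  seed = 1)[[1]]
  }
  o1 <- addTwo("P", "E")
  o2 <- addTwo("E", "P")
  ## name-independent comparison: the multiset of leaf sets below each edge
  splitSets <- function(graph) {
    e <- graph@edges
    leaves <- graphLeaves(graph)
    below <- function(nd) {
      out <- character(0); frontier <- nd
      while (length(frontier)) {
        out <- union(out, frontier)
        frontier <- e$child[e$parent %in% frontier]
      }
      sort(intersect(out, leaves))
    }
    sort(vapply(e$child, function(nd) paste(below(nd), collapse = ","),
                character(1)))
  }
  expect_false(identical(splitSets(o1$fit$graph), splitSets(o2$fit$graph)))
})
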