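## Least-squares admixture-graph fitting.  Expected f2 between leaves is
## computed from the graph by the covariance recursion: each leaf carries a
## vector of expected edge traversals (admixture nodes mix parental vectors
## by alpha, so covariances pick up alpha^2 weights), and
## E f2(X, Y) = sum_e c_e (u_X(e) - u_Y(e))^2 with drift lengths c_e in f2
## units.  Drift lengths are constrained >= 0 and mixing weights to [0, 1].

## leaf-by-edge expected traversal matrix for given alpha values
.edgeUsage <- function(edges, admixture) {
  ord <- .topoOrder(edges)
  U <- matrix(0, length(ord), nrow(edges), dimnames = list(ord, NULL))
  root <- setdiff(edges$parent, edges$child)
  for (nd in ord) {
    if (nd == root) next
    if (nd %in% admixture$child) {
      i <- match(nd, admixture$child)
      a <- admixture$alpha[i]
      eA <- which(edges$parent == admixture$parentA[i] & edges$child == nd)
      eB <- which(edges$parent == admixture$parentB[i] & edges$child == nd)
      U[nd, ] <- a * U[admixture$parentA[i], ] +
                 (1 - a) * U[admixture$parentB[i], ]
      U[nd, eA] <- U[nd, eA] + a
      U[nd, eB] <- U[nd, eB] + (1 - a)
    } else {
      i <- which(edges$child == nd)
      U[nd, ] <- U[edges$parent[i], ]
      U[nd, i] <- U[nd, i] + 1
    }
  }
  U
}

## expected f2 vector for leaf pairs given drift c and usage matrix
.expectedF2 <- function(U, cdrift, pairs) {
  vapply(seq_len(nrow(pairs)), function(k) {
    du <- U[pairs[k, 1], ] - U[pairs[k, 2], ]
    sum(cdrift * du * du)
  }, numeric(1))
}

## observed f2 basis (all leaf pairs) with jackknife covariance
.f2Basis <- function(ac, leaves, blocks, corrected = TRUE) {
  pairs <- t(combn(leaves, 2))
  Bn <- max(blocks)
  E <- nrow(pairs)
  S <- K <- matrix(0, E, Bn)
  for (e in seq_len(E)) {
    per <- .fstatPerSnp(ac, "f2", pairs[e, ],
                        corrected && all(ac@ploidy[pairs[e, ]] == 2L))
    v <- ifelse(per$use, per$values, 0)
    S[e, ] <- as.vector(rowsum(v, blocks))
    K[e, ] <- as.vector(rowsum(as.numeric(per$use), blocks))
  }
  tS <- rowSums(S); tK <- rowSums(K)
  est <- tS / tK
  loo <- t((tS - S) / (tK - K))
  if (any(!is.finite(loo)))
    loo[!is.finite(loo)] <- rep(est, each = Bn)[!is.finite(loo)]
  m <- tabulate(blocks, nbins = Bn)
  jk <- .jackknifeCov(est, loo, m)
  list(pairs = pairs, est = est, Q = jk$cov, loo = loo, m = m)
}

#' Fit drift lengths and admixture weights of a graph topology
#'
#' Bounded weighted least squares: drift lengths (>= 0, in f2 units) and
#' admixture weights (in `[0, 1]`) minimize the Mahalanobis distance
#' between observed and expected f2 statistics over all leaf pairs, with
#' the jackknife covariance of the basis as weight matrix. Residual
#' z-scores use the covariance diagonal; the fit score is the number of
#' `|z| > 2`. A fitted zero-length branch is reported, not an error. Graphs
#' whose parameters are not all identifiable from the f2 basis are
#' reported with the dimension of the unidentifiable (null) space.
#'
#' @param graph An [AdmixtureGraph-class] giving the topology; its drift
#'   and alpha values are used as one starting point.
#' @param ac An [AlleleCounts-class] covering every leaf.
#' @param blocks Block ids from [assignBlocks()].
#' @param corrected Bias-correct observed f2 where ploidy permits.
#' @param nStarts Random restarts of the admixture-weight search.
#' @param seed Seed for the restarts.
#' @param basis Precomputed result of the internal f2-basis builder over
#'   the same leaves (used by [greedyAddLeaf()] to share one basis across
#'   candidate topologies); leave `NULL` normally.
#' @return An object of class `graphFit`: list with `graph` (fitted),
#'   `score`, `fit` (per-pair observed/fitted/z table), `value`
#'   (minimized objective), `paramSE` (delta-method SEs), `nullSpaceDim`.
#' @export
fitGraph <- function(graph, ac, blocks, corrected = TRUE, nStarts = 3L,
                     seed = 1L, basis = NULL) {
  leaves <- graphLeaves(graph)
  stopifnot(all(leaves %in% populations(ac)))
  if (is.null(basis)) basis <- .f2Basis(ac, leaves, blocks, corrected)
  stopifnot(identical(sort(unique(as.vector(basis$pairs))), leaves))
  Qinv <- .solveRidge(basis$Q)
  Wchol <- chol(Qinv)
  e <- graph@edges; adm <- graph@admixture
  nE <- nrow(e); nA <- nrow(adm)
  ## edges may carry a logical `fixed` column pinning their drift (e.g.
  ## zero-length admixture legs); only free drifts are fitted
  fixedE <- if (!is.null(e$fixed)) as.logical(e$fixed) else rep(FALSE, nE)
  freeE <- which(!fixedE)
  ## design matrix over edges for given alphas: rows = pairs, cols = edges
  design <- function(a2) {
    U <- .edgeUsage(e, a2)
    DU <- U[basis$pairs[, 1], , drop = FALSE] -
          U[basis$pairs[, 2], , drop = FALSE]
    DU * DU
  }
  ## for fixed alphas the model is linear in drift: bounded (>= 0) GLS
  innerFit <- function(alphas) {
    a2 <- adm; if (nA) a2$alpha <- alphas
    D <- design(a2)
    off <- if (any(fixedE))
      D[, fixedE, drop = FALSE] %*% e$drift[fixedE] else 0
    A <- Wchol %*% D[, freeE, drop = FALSE]
    b <- drop(Wchol %*% (basis$est - off))
    ns <- pracma::lsqnonneg(A, b)
    list(drift = ns$x, value = sum((b - drop(A %*% ns$x))^2), a2 = a2)
  }
  if (nA == 0) {
    best <- innerFit(numeric(0))
  } else {
    aobj <- function(alphas) innerFit(alphas)$value
    starts <- list(pmin(pmax(adm$alpha, 0.05), 0.95))
    for (s in seq_len(max(0, nStarts - 1)))
      starts[[s + 1]] <- withSeed(subSeed(seed, "graphfit", s),
                                  runif(nA, 0.05, 0.95))
    bestA <- NULL
    for (a0 in starts) {
      op <- tryCatch(
        optim(a0, aobj, method = "L-BFGS-B", lower = rep(0, nA),
              upper = rep(1, nA), control = list(maxit = 200)),
        error = function(err) NULL)
      if (!is.null(op) && (is.null(bestA) || op$value < bestA$value))
        bestA <- op
    }
    if (is.null(bestA)) stop("graph fit failed from every start")
    best <- innerFit(pmin(pmax(bestA$par, 0), 1))
  }
  scale0 <- max(mean(abs(basis$est)), 1e-6)
  th <- c(best$drift, if (nA) best$a2$alpha)
  lower <- c(rep(0, length(freeE)), rep(0, nA))
  eFit <- e; eFit$drift[freeE] <- best$drift
  aFit <- best$a2
  U <- .edgeUsage(eFit, aFit)
  fitted <- .expectedF2(U, eFit$drift, basis$pairs)
  r <- basis$est - fitted
  z <- r / sqrt(diag(basis$Q))
  ## numeric Jacobian for identifiability and delta-method SEs
  pred <- function(theta) {
    cd <- e$drift
    cd[freeE] <- theta[seq_along(freeE)]
    a2 <- adm; if (nA) a2$alpha <- theta[length(freeE) + seq_len(nA)]
    .expectedF2(.edgeUsage(e, a2), cd, basis$pairs)
  }
  hstep <- pmax(abs(th), scale0) * 1e-5
  J <- vapply(seq_along(th), function(i) {
    tp <- th; tp[i] <- tp[i] + hstep[i]
    tm <- th; tm[i] <- pmax(tm[i] - hstep[i], lower[i])
    (pred(tp) - pred(tm)) / (tp[i] - tm[i])
  }, numeric(length(basis$est)))
  sv <- svd(J)
  rankJ <- sum(sv$d > max(sv$d) * 1e-8)
  JtQJ <- t(J) %*% Qinv %*% J
  covTheta <- tryCatch({
    ei <- eigen(JtQJ, symmetric = TRUE)
    keep <- ei$values > max(ei$values) * 1e-10
    ei$vectors[, keep, drop = FALSE] %*%
      diag(1 / ei$values[keep], sum(keep)) %*%
      t(ei$vectors[, keep, drop = FALSE])
  }, error = function(err) matrix(NA_real_, length(th), length(th)))
  paramSE <- sqrt(pmax(diag(covTheta), 0))
  names(paramSE) <- c(sprintf("%s->%s", e$parent[freeE], e$child[freeE]),
                      if (nA) sprintf("alpha[%s]", adm$child))
  gFit <- AdmixtureGraph(eFit, if (nA) aFit else NULL)
  structure(list(graph = gFit, score = sum(abs(z) > 2, na.rm = TRUE),
                 fit = data.frame(popA = basis$pairs[, 1],
                                  popB = basis$pairs[, 2],
                                  observed = basis$est, fitted = fitted,
                                  z = z),
                 value = best$value, paramSE = paramSE,
                 nullSpaceDim = length(th) - rankJ),
            class = "graphFit")
}

#' @export
print.graphFit <- function(x, ...) {
  cat(sprintf("graphFit: score %d (|z| > 2 of %d statistics), objective %.3g\n",
              x$score, nrow(x$fit), x$value))
  if (x$nullSpaceDim > 0)
    cat(sprintf("  note: %d unidentifiable parameter direction(s)\n",
                x$nullSpaceDim))
  worst <- x$fit[order(-abs(x$fit$z)), ][1, ]
  cat(sprintf("  worst residual: f2(%s, %s) z = %.2f\n",
              worst$popA, worst$popB, worst$z))
  invisible(x)
}

## split edge (parent -> child) by inserting `node` midway
.splitEdge <- function(graph, parent, child, node) {
  e <- graph@edges
  i <- which(e$parent == parent & e$child == child)
  stopifnot(length(i) == 1)
  d <- e$drift[i] / 2
  fx <- e$fixed[i]
  e <- e[-i, , drop = FALSE]
  e <- rbind(e,
             data.frame(parent = parent, child = node, drift = d, fixed = fx),
             data.frame(parent = node, child = child, drift = d, fixed = fx))
  a <- graph@admixture
  if (nrow(a)) {
    ## the split edge may feed an admixture node: repoint its parent
    hitA <- a$child == child & a$parentA == parent
    hitB <- a$child == child & a$parentB == parent
    a$parentA[hitA] <- node
    a$parentB[hitB] <- node
  }
  AdmixtureGraph(e, if (nrow(a)) a else NULL)
}

#' Greedy addition of a new leaf to a fitted graph
#'
#' Enumerates every attachment of `newPop` to the base topology: as a
#' plain leaf hanging off each single edge, and as a two-way admixture of
#' each unordered pair of edges. Every candidate is refitted and the
#' candidates are ranked by fit score, then parsimony (fewer admixture
#' events, then fewer zero-length internal branches), then the residual
#' objective. The search is greedy: the outcome can depend on the order in
#' which successive populations are added.
#'
#' @param graph Base [AdmixtureGraph-class] topology.
#' @param newPop Population to add (present in `ac`).
#' @param ac An [AlleleCounts-class].
#' @param blocks Block ids.
#' @param corrected Bias-correct observed f2 where ploidy permits.
#' @param ... Passed to [fitGraph()].
#' @return A list of candidate fits, best first; each element has
#'   `attachment` (a description), `fit` (the `graphFit`) and the ranking
#'   fields `score`, `nAdmix`, `zeroInternal`, `value`.
#' @export
greedyAddLeaf <- function(graph, newPop, ac, blocks, corrected = TRUE, ...) {
  allLeaves <- sort(c(graphLeaves(graph), newPop))
  basis <- .f2Basis(ac, allLeaves, blocks, corrected)
  e <- graph@edges
  Ecnt <- nrow(e)
  cands <- list()
  for (i in seq_len(Ecnt)) {
    nd <- sprintf("%s_split%d", newPop, i)
    g2 <- .splitEdge(graph, e$parent[i], e$child[i], nd)
    g2 <- AdmixtureGraph(rbind(g2@edges,
                               data.frame(parent = nd, child = newPop,
                                          drift = 0.001, fixed = FALSE)),
                         if (nrow(g2@admixture)) g2@admixture else NULL)
    cands[[length(cands) + 1]] <- list(
      attachment = sprintf("edge %s->%s", e$parent[i], e$child[i]),
      graph = g2)
  }
  if (Ecnt >= 2) for (i in seq_len(Ecnt - 1)) for (j in (i + 1):Ecnt) {
    ndA <- sprintf("%s_splitA%d_%d", newPop, i, j)
    ndB <- sprintf("%s_splitB%d_%d", newPop, i, j)
    mix <- sprintf("%s_mix%d_%d", newPop, i, j)
    g2 <- .splitEdge(graph, e$parent[i], e$child[i], ndA)
    g2 <- .splitEdge(g2, e$parent[j], e$child[j], ndB)
    ed <- rbind(g2@edges,
                data.frame(parent = c(ndA, ndB, mix),
                           child = c(mix, mix, newPop),
                           drift = c(0, 0, 0.001), fixed = FALSE))
    ad <- rbind(g2@admixture,
                data.frame(child = mix, parentA = ndA, parentB = ndB,
                           alpha = 0.5))
    g2 <- AdmixtureGraph(ed, ad)
    cands[[length(cands) + 1]] <- list(
      attachment = sprintf("admixture of %s->%s and %s->%s",
                           e$parent[i], e$child[i], e$parent[j], e$child[j]),
      graph = g2)
  }
  out <- lapply(cands, function(cd) {
    ft <- fitGraph(cd$graph, ac, blocks, corrected = corrected,
                   basis = basis, ...)
    eF <- ft$graph@edges
    leaves <- graphLeaves(ft$graph)
    internal <- !(eF$child %in% leaves)
    list(attachment = cd$attachment, fit = ft, score = ft$score,
         nAdmix = nrow(ft$graph@admixture),
         zeroInternal = sum(internal & eF$drift < 1e-5),
         value = ft$value)
  })
  ord <- order(vapply(out, `[[`, 0, "score"),
               vapply(out, `[[`, 0, "nAdmix"),
               vapply(out, `[[`, 0, "zeroInternal"),
               vapply(out, `[[`, 0, "value"))
  out[ord]
}
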