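## qpWave-style rank tests on a matrix of f4 statistics: how many
## independent ancestry streams relate a set of "left" populations to a
## set of "right" outgroups.

#' Build the f4 matrix and its jackknife covariance
#'
#' `X[i, j] = f4(l0, l_i; r0, r_j)` for left populations `l0, l1, ...`
#' (target/reference first) and right populations `r0, r1, ...`
#' (reference outgroup first). With `allsnps = TRUE` (the default, the
#' "allsnps: YES" behaviour) each entry uses its own maximal set of SNPs
#' where all four argument populations are covered; with `FALSE` all
#' entries use the global intersection across left and right populations.
#' The covariance `Q` of `vec(X)` (column-major) comes from the weighted
#' block jackknife over genetic-map blocks.
#'
#' @param ac An [AlleleCounts-class].
#' @param left,right Population name vectors (`left` and `right` must be
#'   disjoint; at least 2 right populations beyond the reference).
#' @param blocks Block ids from [assignBlocks()].
#' @param allsnps Per-entry maximal SNP sets (TRUE) or global intersection.
#' @return An object of class `f4matrix`: a list with `X` (the
#'   `(L-1) x (R-1)` matrix), `est` (= `vec(X)`), `loo` (B x E
#'   leave-one-block-out estimates), `Q`, `m` (block weights), `left`,
#'   `right`.
#' @export
buildF4Matrix <- function(ac, left, right, blocks, allsnps = TRUE) {
  stopifnot(is(ac, "AlleleCounts"))
  if (length(intersect(left, right)))
    stop("left and right population sets must be disjoint")
  if (length(right) < 3) stop("need at least 2 right populations beyond the reference")
  pops <- c(left, right)
  stopifnot(all(pops %in% populations(ac)))
  N <- ac@n[pops, , drop = FALSE]
  f <- ac@x[pops, , drop = FALSE] / N
  L <- length(left); R <- length(right)
  E <- (L - 1) * (R - 1)
  Bn <- max(blocks)
  if (Bn < 2) stop("need at least 2 jackknife blocks")
  globalUse <- colSums(N >= 1) == length(pops)
  if (!allsnps && !any(globalUse))
    stop("no SNPs covered by every population (allsnps = FALSE)")
  S <- matrix(0, E, Bn); K <- matrix(0, E, Bn)
  dl0 <- f[left[1], ]; dr0 <- f[right[1], ]
  e <- 0L
  for (j in 2:R) for (i in 2:L) {
    e <- e + 1L
    v <- (dl0 - f[left[i], ]) * (dr0 - f[right[j], ])
    use <- if (allsnps) {
      N[left[1], ] >= 1 & N[left[i], ] >= 1 &
      N[right[1], ] >= 1 & N[right[j], ] >= 1
    } else globalUse
    if (!any(use)) stop(sprintf("no usable SNPs for entry (%s, %s)",
                                left[i], right[j]))
    S[e, ] <- as.vector(rowsum(ifelse(use, v, 0), blocks,
                               reorder = TRUE))[seq_len(Bn)]
    K[e, ] <- as.vector(rowsum(as.numeric(use), blocks,
                               reorder = TRUE))[seq_len(Bn)]
  }
  tS <- rowSums(S); tK <- rowSums(K)
  est <- tS / tK
  loo <- t((tS - S) / (tK - K))  # B x E
  if (any(!is.finite(loo)))      # a block holding all usable SNPs of an entry
    loo[!is.finite(loo)] <- rep(est, each = Bn)[!is.finite(loo)]
  m <- tabulate(blocks, nbins = Bn)
  jk <- .jackknifeCov(est, loo, m)
  structure(list(X = matrix(est, L - 1, R - 1,
                            dimnames = list(left[-1], right[-1])),
                 est = est, loo = loo, Q = jk$cov, m = m,
                 left = left, right = right, allsnps = allsnps,
                 nSnps = round(mean(tK))),
            class = "f4matrix")
}

#' @export
print.f4matrix <- function(x, ...) {
  cat(sprintf("f4 matrix: left (%s) x right (%s), ~%d SNPs/entry\n",
              paste(x$left, collapse = ","), paste(x$right, collapse = ","),
              x$nSnps))
  print(x$X)
  invisible(x)
}

## inverse with escalating ridge regularization
.solveRidge <- function(Q, eps = 1e-6, maxEps = 1e-3) {
  d <- mean(diag(Q))
  while (eps <= maxEps) {
    Qr <- Q + diag(eps * d, nrow(Q))
    inv <- tryCatch(solve(Qr), error = function(e) NULL)
    if (!is.null(inv) && kappa(Qr) < 1e12) return(inv)
    eps <- eps * 10
  }
  stop(sprintf("covariance is singular even after ridge regularization (condition number %.3g)",
               kappa(Q + diag(maxEps * d, nrow(Q)))))
}

#' qpWave rank test
#'
#' Tests whether the f4 matrix is consistent with rank `r`, i.e. with
#' `r + 1` independent ancestry streams relating left to right
#' populations. The statistic is the minimum of
#' `(vec(X - Xhat))' Qinv (vec(X - Xhat))` over rank-`r` matrices `Xhat`,
#' found by alternating generalized least squares with seeded random
#' restarts, on `df = (L - 1 - r)(R - 1 - r)` degrees of freedom.
#'
#' Because `Q` is itself estimated from a finite number of jackknife
#' blocks, the quadratic form is referred to a Hotelling-style F
#' distribution (`T^2` with `nBlocks - 1` covariance degrees of freedom)
#' rather than the asymptotic chi-square; the two agree as the block
#' count grows. When the block count is unknown the chi-square reference
#' is used.
#'
#' @param f4m An `f4matrix` from [buildF4Matrix()], or a plain matrix
#'   (then `Q` must be given).
#' @param rank Rank(s) to test; default all of `0:(min(dim) - 1)`.
#' @param Q Covariance of `vec(X)` when `f4m` is a plain matrix.
#' @param nBlocks Number of jackknife blocks behind `Q` (taken from
#'   `f4m` automatically); `NULL` falls back to the chi-square reference.
#' @param nRestarts Random restarts of the alternating minimization.
#' @param seed Seed for the restarts.
#' @return A `data.frame` with `rank`, `statistic`, `df`, `p`.
#' @export
qpWaveTest <- function(f4m, rank = NULL, Q = NULL, nBlocks = NULL,
                       nRestarts = 10L, seed = 1L) {
  if (inherits(f4m, "f4matrix")) {
    X <- f4m$X; Q <- f4m$Q
    if (is.null(nBlocks)) nBlocks <- length(f4m$m)
  } else X <- f4m
  stopifnot(!is.null(Q))
  m <- nrow(X); n <- ncol(X)
  if (is.null(rank)) rank <- 0:(min(m, n) - 1)
  Qinv <- .solveRidge(Q)
  x <- as.vector(X)
  out <- lapply(rank, function(r) {
    stopifnot(r >= 0, r < min(m, n))
    stat <- if (r == 0) {
      drop(t(x) %*% Qinv %*% x)
    } else {
      best <- Inf
      for (s in seq_len(nRestarts)) {
        A <- withSeed(subSeed(seed, "qpwave", r, s),
                      matrix(rnorm(m * r), m, r))
        val <- .alsRankFit(x, m, n, r, A, Qinv)
        if (val < best) best <- val
      }
      best
    }
    df <- (m - r) * (n - r)
    p <- if (!is.null(nBlocks) && nBlocks - df >= 2) {
      nu <- nBlocks - 1
      stats::pf(stat * (nu - df + 1) / (nu * df), df, nu - df + 1,
                lower.tail = FALSE)
    } else {
      pchisq(stat, df, lower.tail = FALSE)
    }
    data.frame(rank = r, statistic = stat, df = df, p = p)
  })
  do.call(rbind, out)
}

## GLS normal-equation solve robust to rank deficiency (degenerate factors)
.glsStep <- function(M, Qinv, x) {
  N <- t(M) %*% Qinv %*% M
  rhs <- t(M) %*% Qinv %*% x
  d <- mean(diag(N))
  if (!is.finite(d) || d <= 0) return(rep(0, ncol(M)))
  tryCatch(solve(N, rhs),
           error = function(e) solve(N + diag(1e-10 * d, ncol(M)), rhs))
}

## alternating GLS for min over rank-r Xhat = A B' of the Mahalanobis norm
.alsRankFit <- function(x, m, n, r, A, Qinv, maxIter = 100L, tol = 1e-10) {
  val <- Inf
  for (it in seq_len(maxIter)) {
    ## fix A, solve for B: vec(AB') = (I_n %x% A) vec(B')
    MB <- diag(n) %x% A
    bt <- .glsStep(MB, Qinv, x)
    Bm <- matrix(bt, r, n)  # B' is r x n
    ## fix B, solve for A: vec(AB') = (B %x% I_m) vec(A)
    MA <- t(Bm) %x% diag(m)
    at <- .glsStep(MA, Qinv, x)
    A <- matrix(at, m, r)
    res <- x - as.vector(A %*% Bm)
    new <- drop(t(res) %*% Qinv %*% res)
    if (is.finite(val) && abs(val - new) < tol * (1 + abs(new))) {
      val <- new; break
    }
    val <- new
  }
  val
}
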