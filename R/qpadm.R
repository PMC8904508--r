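#' qpAdm admixture-weight estimation
#'
#' Models a target population as a mixture of source populations relative
#' to a set of right outgroups. With the f4 matrix rows
#' `X[i, j] = f4(target, source_i; r0, r_j)`, the mixture condition is
#' `sum_i w_i X[i, j] = 0` for every right outgroup `j`, and the weights
#' solve the generalized least squares problem
#' `min_w w' X Omega^-1 X' w` subject to `sum w = 1`, where `Omega` is the
#' jackknife covariance of the contrast vector (iterated once from uniform
#' starting weights). Standard errors re-run the whole solve on each
#' leave-one-block-out f4 matrix. The tail p-value is the qpWave rank test
#' of the full left set at rank `nSources - 1`: a small value means even
#' the best mixture cannot reconcile target and sources with the rights.
#' Weights outside `[0, 1]` are reported as infeasible, not clamped.
#'
#' @param ac An [AlleleCounts-class].
#' @param target Target population name.
#' @param sources Character vector of source populations (>= 2).
#' @param rights Right (outgroup) populations, reference first.
#' @param blocks Block ids from [assignBlocks()].
#' @param allsnps Per-statistic maximal SNP sets (default TRUE).
#' @return An object of class `qpAdmFit`: list with `weights`, `se`,
#'   `p` (tail probability), `feasible`, `diagnostics`.
#' @export
qpAdm <- function(ac, target, sources, rights, blocks, allsnps = TRUE) {
  if (length(sources) < 2) stop("need at least 2 sources")
  if (anyDuplicated(c(target, sources)))
    stop("collinear sources: duplicated population in the left set")
  f4m <- buildF4Matrix(ac, left = c(target, sources), right = rights,
                       blocks = blocks, allsnps = allsnps)
  k <- length(sources); Rm1 <- length(rights) - 1
  solveW <- function(estVec, Q) {
    X <- matrix(estVec, k, Rm1)
    w <- rep(1 / k, k)
    for (it in 1:3) {
      ## Omega = cov of d_j = sum_i w_i X_ij under vec(X) covariance Q
      W <- matrix(0, k * Rm1, Rm1)
      for (j in seq_len(Rm1)) W[(j - 1) * k + seq_len(k), j] <- w
      Omega <- t(W) %*% Q %*% W
      Oinv <- .solveRidge(Omega)
      M <- X %*% Oinv %*% t(X)
      Minv <- tryCatch(solve(M), error = function(e) {
        cr <- suppressWarnings(stats::cor(t(X)))
        diag(cr) <- 0
        ij <- which(abs(cr) == max(abs(cr)), arr.ind = TRUE)[1, ]
        stop(sprintf("collinear sources: %s and %s give indistinguishable f4 profiles",
                     sources[ij[1]], sources[ij[2]]))
      })
      one <- rep(1, k)
      w <- drop(Minv %*% one) / drop(t(one) %*% Minv %*% one)
    }
    w
  }
  w <- solveW(f4m$est, f4m$Q)
  ## jackknife of the whole solve
  B <- nrow(f4m$loo)
  wLoo <- t(vapply(seq_len(B), function(b) solveW(f4m$loo[b, ], f4m$Q),
                   numeric(k)))
  se <- vapply(seq_len(k), function(i)
    .jackknife(w[i], wLoo[, i], f4m$m)$se, numeric(1))
  rk <- qpWaveTest(f4m, rank = k - 1)
  names(w) <- names(se) <- sources
  blowup <- any(se > 1)
  structure(list(target = target, sources = sources, rights = rights,
                 weights = w, se = se, p = rk$p, statistic = rk$statistic,
                 df = rk$df, feasible = all(w >= 0 & w <= 1),
                 diagnostics = list(
                   se_blowup = blowup,
                   note = if (blowup)
                     "standard errors blow up: the right set does not differentiate the sources"
                   else NULL),
                 f4matrix = f4m),
            class = "qpAdmFit")
}

#' @export
print.qpAdmFit <- function(x, ...) {
  cat(sprintf("qpAdm: %s = %s\n", x$target,
              paste(sprintf("%.3f (SE %.3f) %s", x$weights, x$se,
                            x$sources), collapse = " + ")))
  cat(sprintf("  tail p = %.4g (rank %d, df %d)%s\n", x$p,
              length(x$sources) - 1, x$df,
              if (x$feasible) "" else "  [INFEASIBLE: weights outside [0,1]]"))
  if (isTRUE(x$diagnostics$se_blowup)) cat("  warning:", x$diagnostics$note, "\n")
  invisible(x)
}

#' qpWave cladality / stream-count test between population sets
#'
#' Convenience wrapper: builds the f4 matrix for `left` vs `right` and
#' returns the rank-test table. A high rank-0 p-value for
#' `left = c(A, B)` means A and B are cladal (form one stream) relative
#' to the rights.
#'
#' @inheritParams buildF4Matrix
#' @param ... Passed to [qpWaveTest()].
#' @return A `data.frame` of rank tests.
#' @export
qpWave <- function(ac, left, right, blocks, allsnps = TRUE, ...) {
  f4m <- buildF4Matrix(ac, left, right, blocks, allsnps)
  qpWaveTest(f4m, ...)
}
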