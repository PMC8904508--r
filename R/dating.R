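## Admixture dating from ancestry-covariance decay.  In an admixed
## population, linkage between ancestry-informative alleles decays as
## exp(-g d) with genetic distance d (Morgans) at a rate equal to the
## number of generations g since admixture.

#' Weighted ancestry-covariance decay curve
#'
#' For every SNP, the ancestry-informative weight is the source frequency
#' difference `w = p1 - p2`, and the per-individual residual equals
#' `geno/2 - (p1 + p2)/2`. For every SNP pair on the same chromosome
#' with genetic distance `d` in `(0, maxDistCM]`, the product
#' `w_k w_l cov_i(r_k, r_l)` (covariance across individuals; plain
#' product for a single individual) is accumulated into the distance bin
#' of `d`. Bin `i` covers `[i * binsizeCM, (i+1) * binsizeCM)` cM.
#'
#' @param target A [CallMatrix-class] of the admixed target individuals
#'   (diploid genotypes, or pseudo-haploid calls counted as dosage 0/2).
#' @param p1,p2 Reference allele-frequency vectors over the panel (e.g.
#'   rows of a [FreqTable-class], or sample frequencies).
#' @param binsizeCM Bin width in cM (default 0.01).
#' @param maxDistCM Maximum pair distance in cM (default 1).
#' @return An object of class `decayCurve`: list with `binLeftCM`,
#'   `value` (per-bin mean weighted covariance), `nPairs`, and the
#'   per-chromosome `sums`/`counts` matrices used for jackknifing.
#' @export
ancestryCovariance <- function(target, p1, p2, binsizeCM = 0.01,
                               maxDistCM = 1.0) {
  stopifnot(is(target, "CallMatrix"))
  s <- snpInfo(target)
  m <- calls(target)
  if (ploidy(target) == 1L) m <- 2L * m
  w <- p1 - p2
  if (all(w == 0)) {
    nb <- ceiling(maxDistCM / binsizeCM)
    return(structure(list(binLeftCM = (seq_len(nb) - 1) * binsizeCM,
                          value = rep(0, nb), nPairs = rep(0, nb),
                          sums = matrix(0, nb, 1), counts = matrix(0, nb, 1),
                          binsizeCM = binsizeCM, chroms = "none"),
                     class = "decayCurve"))
  }
  I <- ncol(m)
  r <- m / 2 - (p1 + p2) / 2        # SNPs x individuals
  r[is.na(r)] <- 0                  # missing calls contribute nothing
  if (I > 1) r <- r - rowMeans(r)   # center across individuals
  binM <- binsizeCM / 100
  maxM <- maxDistCM / 100
  nb <- ceiling(maxDistCM / binsizeCM)
  chroms <- unique(s$chrom)
  sums <- matrix(0, nb, length(chroms), dimnames = list(NULL, chroms))
  counts <- sums
  any_pairs <- FALSE
  for (ci in seq_along(chroms)) {
    ix <- which(s$chrom == chroms[ci])
    g <- s$gpos[ix]
    rc <- r[ix, , drop = FALSE]
    wv <- w[ix]
    n <- length(ix)
    for (k in seq_len(n - 1)) {
      d <- g[(k + 1):n] - g[seq_len(n - k)]
      if (min(d) > maxM) break
      keep <- d > 0 & d <= maxM
      if (!any(keep)) next
      any_pairs <- TRUE
      i1 <- which(keep)
      i2 <- i1 + k
      cv <- rowSums(rc[i1, , drop = FALSE] * rc[i2, , drop = FALSE])
      cv <- if (I > 1) cv / (I - 1) else cv
      contrib <- wv[i1] * wv[i2] * cv
      bin <- pmin(floor(d[keep] / binM) + 1L, nb)
      sb <- rowsum(contrib, bin)
      ub <- as.integer(rownames(sb))
      sums[ub, ci] <- sums[ub, ci] + sb[, 1]
      counts[, ci] <- counts[, ci] + tabulate(bin, nbins = nb)
    }
  }
  if (!any_pairs) stop("no SNP pairs within the distance window")
  tot <- rowSums(counts)
  structure(list(binLeftCM = (seq_len(nb) - 1) * binsizeCM,
                 value = ifelse(tot > 0, rowSums(sums) / tot, NA_real_),
                 nPairs = tot, sums = sums, counts = counts,
                 binsizeCM = binsizeCM, chroms = chroms),
            class = "decayCurve")
}

#' @export
print.decayCurve <- function(x, ...) {
  cat(sprintf("decayCurve: %d bins of %.3g cM, %d chromosome(s), %g pairs\n",
              length(x$binLeftCM), x$binsizeCM, ncol(x$sums), sum(x$nPairs)))
  invisible(x)
}

#' @export
plot.decayCurve <- function(x, ...) {
  plot(x$binLeftCM + x$binsizeCM / 2, x$value, xlab = "distance (cM)",
       ylab = "weighted ancestry covariance", ...)
}

## exponential-plus-offset fit of one curve (bins already selected)
.fitExp <- function(d, y, starts) {
  best <- NULL
  for (g0 in starts) {
    A0 <- max(y[1] - min(y), 1e-8)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-g * d) + c0,
                        start = list(A = A0, g = g0, c0 = min(y)),
                        lower = c(A = 0, g = 1e-6, c0 = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
  }
  best
}

#' Fit the exponential decay and date the admixture
#'
#' Fits `y(d) = A exp(-g d) + c` (distance `d` in Morgans) to the decay
#' curve by nonlinear least squares with multiple starting decay rates,
#' constrained to `A >= 0`, `g > 0`. The decay rate `g` is the admixture
#' age in generations. Its standard error comes from leave-one-chromosome
#' -out refits combined with the weighted jackknife (weights = pair
#' counts). Bins closer than `minDistCM` are excluded from the fit, where
#' background LD contaminates the signal.
#'
#' @param curve A `decayCurve` from [ancestryCovariance()].
#' @param minDistCM Minimum bin distance used (default 0.05 cM).
#' @param starts Starting decay rates in generations.
#' @return An object of class `datesFit`: list with `A`, `g`, `c`,
#'   `se` (of g), `window` (cM), `converged`, `perChrom` (leave-one-out
#'   estimates of g).
#' @export
fitDecay <- function(curve, minDistCM = 0.05, starts = c(5, 20, 50, 200)) {
  ctr <- curve$binLeftCM + curve$binsizeCM / 2
  useBin <- curve$nPairs > 0 & ctr >= minDistCM & !is.na(curve$value)
  if (sum(useBin) < 10) stop("need at least 10 usable bins")
  d <- ctr[useBin] / 100   # Morgans
  y <- curve$value[useBin]
  best <- .fitExp(d, y, starts)
  if (is.null(best))
    return(structure(list(A = NA, g = NA, c = NA, se = NA,
                          window = range(ctr[useBin]), converged = FALSE,
                          perChrom = NULL), class = "datesFit"))
  co <- coef(best$fit)
  nCh <- ncol(curve$sums)
  gLoo <- NULL; se <- NA_real_
  if (nCh >= 2) {
    gLoo <- rep(NA_real_, nCh)
    mW <- colSums(curve$counts)
    for (j in seq_len(nCh)) {
      cnt <- rowSums(curve$counts[, -j, drop = FALSE])
      val <- ifelse(cnt > 0, rowSums(curve$sums[, -j, drop = FALSE]) / cnt, NA)
      ub <- useBin & cnt > 0 & !is.na(val)
      fj <- .fitExp(ctr[ub] / 100, val[ub], starts = c(co[["g"]], starts))
      if (!is.null(fj)) gLoo[j] <- coef(fj$fit)[["g"]]
    }
    okj <- !is.na(gLoo)
    if (sum(okj) >= 2)
      se <- .jackknife(co[["g"]], gLoo[okj], mW[okj])$se
  }
  structure(list(A = co[["A"]], g = co[["g"]], c = co[["c0"]], se = se,
                 window = range(ctr[useBin]), converged = TRUE,
                 perChrom = gLoo),
            class = "datesFit")
}

#' @export
print.datesFit <- function(x, ...) {
  if (!x$converged) { cat("datesFit: did not converge\n"); return(invisible(x)) }
  cat(sprintf("datesFit: g = %.1f generations (SE %.1f), A = %.3g, c = %.3g, window %.2f-%.2f cM\n",
              x$g, x$se, x$A, x$c, x$window[1], x$window[2]))
  invisible(x)
}

#' Convert an admixture age in generations to a calendar date
#'
#' No default generation time is assumed; both the generation time and
#' the sample's own calendar age must be given explicitly.
#'
#' @param g Generations since admixture.
#' @param generationYears Years per generation (explicit, no default).
#' @param sampleYearsBP Age of the dated sample in years before present.
#' @return Years before present of the admixture event.
#' @export
generationsToYearsBP <- function(g, generationYears, sampleYearsBP) {
  sampleYearsBP + g * generationYears
}
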