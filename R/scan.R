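## Sliding-window outgroup-f3 selection scan: quantifies allele-frequency
## differentiation of a present-day target from an ancient panel relative
## to an outgroup, window by window, normalized by the target's
## heterozygosity and converted to z-scores by LD-block resampling.

#' Specify scan windows and inclusion thresholds
#'
#' @param sizeBp Window size in bp (default 500 kb).
#' @param stepBp Step between window starts (default 10 kb); windows are
#'   anchored at multiples of the step from position 0 of each chromosome.
#' @param minSnps Minimum qualifying SNPs for a window to carry statistics
#'   (default 250; windows below it are emitted with statistics absent).
#' @param minAncientInd A SNP qualifies only when strictly more than this
#'   many ancient individuals have a usable call (default 15). Set
#'   `perIndividualReads = TRUE` to instead require each counted
#'   individual to have more than one read (the alternative literal
#'   reading of the coverage rule).
#' @param perIndividualReads See above (default FALSE).
#' @return A list of class `windowSpec`.
#' @export
windowSpec <- function(sizeBp = 500000L, stepBp = 10000L, minSnps = 250L,
                       minAncientInd = 15L, perIndividualReads = FALSE) {
  stopifnot(stepBp <= sizeBp, minSnps >= 1, minAncientInd >= 1)
  structure(list(sizeBp = as.integer(sizeBp), stepBp = as.integer(stepBp),
                 minSnps = as.integer(minSnps),
                 minAncientInd = as.integer(minAncientInd),
                 perIndividualReads = perIndividualReads),
            class = "windowSpec")
}

#' Sliding-window outgroup-f3 scan
#'
#' Per-SNP inclusion: all three populations covered; segregating in the
#' target or the outgroup; strictly more than `minAncientInd` ancient
#' individuals covered. The window raw f3 is the mean per-SNP
#' `(c - a)(c - b) - c(1-c)/(nC - 1)` with `c` the (diploid) target
#' frequency, `a` the ancient and `b` the outgroup frequency; it is
#' normalized by the window's mean target heterozygosity
#' `2 c (1-c) nC / (nC - 1)` to remove its allele-frequency dependence.
#' Windows are half-open `[start, start + size)` on 1-based coordinates.
#'
#' @param ac An [AlleleCounts-class] holding the three populations.
#' @param target,ancient,outgroup Population names; `ancient` must be
#'   pseudo-haploid so its per-SNP `n` counts covered individuals.
#' @param ancientCoverage Optional per-SNP count of ancient individuals
#'   with more than one read (used when `spec$perIndividualReads`).
#' @param spec A [windowSpec()].
#' @return A `data.frame` of class `windowScan`: chrom, start, end,
#'   nSnps, rawF3, het, normF3 (NA where minima unmet).
#' @export
windowScan <- function(ac, target, ancient, outgroup,
                       spec = windowSpec(), ancientCoverage = NULL) {
  stopifnot(is(ac, "AlleleCounts"),
            all(c(target, ancient, outgroup) %in% populations(ac)))
  s <- snpInfo(ac)
  nC <- ac@n[target, ]; xC <- ac@x[target, ]
  nA <- ac@n[ancient, ]; xA <- ac@x[ancient, ]
  nB <- ac@n[outgroup, ]; xB <- ac@x[outgroup, ]
  covered <- nC >= 2 & nA >= 1 & nB >= 1
  cc <- xC / nC; aa <- xA / nA; bb <- xB / nB
  seg <- (xC > 0 & xC < nC) | (xB > 0 & xB < nB)
  ancCov <- if (spec$perIndividualReads) {
    if (is.null(ancientCoverage))
      stop("perIndividualReads = TRUE needs ancientCoverage")
    ancientCoverage
  } else nA  # pseudo-haploid: one called allele per covered individual
  include <- covered & seg & ancCov > spec$minAncientInd
  fval <- (cc - aa) * (cc - bb) - cc * (1 - cc) / (nC - 1)
  hval <- 2 * cc * (1 - cc) * nC / (nC - 1)
  fval[!include] <- 0; hval[!include] <- 0
  out <- list()
  for (ch in unique(s$chrom)) {
    ix <- which(s$chrom == ch)
    pos <- s$pos[ix]
    cf <- cumsum(fval[ix]); chet <- cumsum(hval[ix])
    cn <- cumsum(as.integer(include[ix]))
    lastStart <- (max(pos) %/% spec$stepBp) * spec$stepBp
    startp <- seq(0L, lastStart, by = spec$stepBp)
    endp <- startp + spec$sizeBp
    lo <- findInterval(startp - 0.5, pos)       # SNPs strictly before start
    hi <- findInterval(endp - 0.5, pos)         # SNPs with pos < end
    keepW <- hi > lo                            # window overlaps >= 1 SNP
    lo <- lo[keepW]; hi <- hi[keepW]
    nS <- cn[hi] - ifelse(lo > 0, cn[lo], 0)
    sf <- cf[hi] - ifelse(lo > 0, cf[lo], 0)
    sh <- chet[hi] - ifelse(lo > 0, chet[lo], 0)
    qual <- nS >= spec$minSnps & sh > 0
    raw <- ifelse(qual, sf / nS, NA_real_)
    het <- ifelse(qual, sh / nS, NA_real_)
    out[[ch]] <- data.frame(chrom = ch, start = startp[keepW] + 1L,
                            end = endp[keepW], nSnps = nS,
                            rawF3 = raw, het = het,
                            normF3 = raw / het)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!any(!is.na(res$normF3)))
    stop("no window meets the SNP minimum; window size too small for the SNP spacing")
  class(res) <- c("windowScan", class(res))
  res
}

#' LD-block resampling z-scores for scan windows
#'
#' For each of `nResamples` draws, one qualifying window is sampled per LD
#' block and the mean and SD of the normalized statistic are computed over
#' blocks; the mean/SD are averaged over resamples and every window's
#' z-score is `(value - mean) / SD`. Windows falling outside all blocks
#' are assigned to the nearest block with a warning.
#'
#' @param scan A `windowScan` data.frame.
#' @param ldBlocks A `data.frame` of 1-based inclusive intervals (`chrom`,
#'   `start`, `end`), e.g. from [readBedIntervals()].
#' @param nResamples Resampling draws (default 100). `nResamples = 1`
#'   reproduces a single-draw estimate.
#' @param seed Integer seed.
#' @return The scan with columns `block` and `z` added; the resampling
#'   mean/SD are attached as attributes `resampleMean`, `resampleSD`.
#' @export
ldBlockZscores <- function(scan, ldBlocks, nResamples = 100L, seed = 1L) {
  mid <- (scan$start + scan$end) / 2
  block <- rep(NA_integer_, nrow(scan))
  for (ch in unique(scan$chrom)) {
    wix <- which(scan$chrom == ch)
    bix <- which(ldBlocks$chrom == ch)
    if (!length(bix)) next
    for (k in bix) {
      inb <- wix[mid[wix] >= ldBlocks$start[k] & mid[wix] <= ldBlocks$end[k]]
      block[inb] <- k
    }
    orphan <- wix[is.na(block[wix])]
    if (length(orphan)) {
      ctr <- (ldBlocks$start[bix] + ldBlocks$end[bix]) / 2
      block[orphan] <- bix[vapply(mid[orphan],
                                  function(p) which.min(abs(ctr - p)), 1L)]
    }
  }
  if (any(is.na(block))) {
    warning(sprintf("%d windows on chromosomes without LD blocks assigned to no block",
                    sum(is.na(block))))
  }
  qual <- !is.na(scan$normF3) & !is.na(block)
  usable <- unique(block[qual])
  if (length(usable) < 20)
    stop(sprintf("only %d LD blocks contain a qualifying window (need >= 20)",
                 length(usable)))
  byBlock <- split(which(qual), block[qual])
  mu <- sdv <- numeric(nResamples)
  withSeed(subSeed(seed, "ldblocks"), {
    for (rs in seq_len(nResamples)) {
      pick <- vapply(byBlock, function(ix)
        scan$normF3[ix[sample.int(length(ix), 1)]], numeric(1))
      mu[rs] <- mean(pick)
      sdv[rs] <- sd(pick)
    }
  })
  m <- mean(mu); sdev <- mean(sdv)
  scan$block <- block
  scan$z <- if (sdev > 0) (scan$normF3 - m) / sdev else NA_real_
  if (sdev == 0) warning("degenerate resampling SD of 0; z-scores undefined")
  attr(scan, "resampleMean") <- m
  attr(scan, "resampleSD") <- sdev
  scan
}

#' Call candidate selection regions from scan z-scores
#'
#' Windows exceeding the z threshold are merged when they overlap, and
#' each merged region is annotated with overlapping gene intervals and
#' its maximum-z window.
#'
#' @param scan A `windowScan` with `z` filled.
#' @param zThreshold Z-score threshold (default 4).
#' @param genes Optional gene annotation `data.frame` (`chrom`, `start`,
#'   `end`, `name`), 1-based inclusive (see [readBedIntervals()]).
#' @return A `data.frame` of candidate regions: chrom, start, end, maxZ,
#'   peakStart, peakEnd, nWindows, genes (comma-separated labels).
#' @export
callCandidates <- function(scan, zThreshold = 4, genes = NULL) {
  hit <- scan[!is.na(scan$z) & scan$z > zThreshold, , drop = FALSE]
  if (!nrow(hit))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), maxZ = numeric(0),
                      peakStart = integer(0), peakEnd = integer(0),
                      nWindows = integer(0), genes = character(0)))
  hit <- hit[order(hit$chrom, hit$start), ]
  out <- list()
  cur <- hit[1, ]
  curMax <- cur; n <- 1L
  flush <- function(cur, curMax, n) {
    gl <- ""
    if (!is.null(genes)) {
      ov <- genes$chrom == cur$chrom & genes$start <= cur$end &
            genes$end >= cur$start
      gl <- paste(genes$name[ov], collapse = ",")
    }
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               maxZ = curMax$z, peakStart = curMax$start,
               peakEnd = curMax$end, nWindows = n, genes = gl)
  }
  if (nrow(hit) > 1) for (i in 2:nrow(hit)) {
    h <- hit[i, ]
    if (h$chrom == cur$chrom && h$start <= cur$end + 1L) {
      cur$end <- max(cur$end, h$end)
      n <- n + 1L
      if (h$z > curMax$z) curMax <- h
    } else {
      out[[length(out) + 1]] <- flush(cur, curMax, n)
      cur <- h; curMax <- h; n <- 1L
    }
  }
  out[[length(out) + 1]] <- flush(cur, curMax, n)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Allele frequency with Wilson 95% confidence interval
#'
#' @param ac An [AlleleCounts-class] (or a list with `x`, `n` vectors).
#' @param pop Population name.
#' @param site SNP index or id.
#' @return A list with `frequency`, `lower`, `upper`, `n`.
#' @export
alleleFrequency <- function(ac, pop, site) {
  if (is.character(site)) site <- match(site, snpInfo(ac)$id)
  x <- unname(ac@x[pop, site]); n <- unname(ac@n[pop, site])
  if (n < 1) stop("no called alleles at this site")
  p <- x / n
  zq <- qnorm(0.975)
  den <- 1 + zq^2 / n
  ctr <- (p + zq^2 / (2 * n)) / den
  hw <- zq * sqrt(p * (1 - p) / n + zq^2 / (4 * n^2)) / den
  list(frequency = p, lower = max(0, ctr - hw), upper = min(1, ctr + hw),
       n = n)
}

#' Genome-wide scan plot
#'
#' @param scan A `windowScan` with z-scores.
#' @param zThreshold Threshold line (default 4).
#' @export
plotScan <- function(scan, zThreshold = 4) {
  ok <- !is.na(scan$z)
  chf <- factor(scan$chrom[ok])
  plot(seq_len(sum(ok)), scan$z[ok], col = as.integer(chf) %% 2 + 1,
       pch = 16, cex = 0.4, xlab = "window", ylab = "z")
  graphics::abline(h = zThreshold, lty = 2)
}
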