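#' Partition a SNP panel into contiguous genetic-distance blocks
#'
#' Blocks span `sizeCM` centimorgans (default 5) of the genetic map,
#' counted from the first SNP of each chromosome, and are the resampling
#' unit for jackknife standard errors. SNPs without a genetic position are
#' interpolated at 1 cM per Mb from their physical position.
#'
#' @param panel A [SNPPanel-class].
#' @param sizeCM Block span in cM.
#' @return An integer vector of block ids (1..B) per SNP, with attribute
#'   `counts` giving per-block SNP counts.
#' @export
assignBlocks <- function(panel, sizeCM = 5) {
  s <- snpInfo(panel)
  g <- s$gpos
  na <- is.na(g)
  g[na] <- s$pos[na] * 1e-8
  sizeM <- sizeCM / 100
  key <- character(nrow(s))
  for (ch in unique(s$chrom)) {
    ix <- s$chrom == ch
    key[ix] <- sprintf("%s_%06d", ch, floor((g[ix] - min(g[ix])) / sizeM))
  }
  id <- as.integer(factor(key, levels = unique(key)))
  counts <- tabulate(id)
  structure(id, counts = counts)
}

#' Weighted block jackknife of a per-SNP statistic
#'
#' Delete-one-block estimates are combined with the weighted jackknife
#' (block weights = SNP counts), which reduces to the plain delete-1
#' jackknife for equal block sizes. The estimate itself is the mean over
#' all SNPs.
#'
#' @param values Per-SNP statistic values (contributing SNPs only).
#' @param blocks Block id per value.
#' @param weights Optional per-SNP weights (default 1).
#' @return A list with `estimate`, `se`, `loo` (leave-one-block-out
#'   estimates), `blockSums`, `blockCounts`.
#' @export
blockJackknife <- function(values, blocks, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(values) == length(blocks))
  blocks <- as.integer(factor(blocks))
  B <- max(blocks)
  if (B < 2) stop("need at least 2 non-empty blocks for a jackknife SE")
  sv <- as.vector(rowsum(values * weights, blocks))
  sw <- as.vector(rowsum(weights, blocks))
  tot <- sum(sv); wtot <- sum(sw)
  est <- tot / wtot
  loo <- (tot - sv) / (wtot - sw)
  jk <- .jackknife(est, loo, sw)
  list(estimate = est, se = jk$se, loo = loo,
       blockSums = sv, blockCounts = sw)
}

## Weighted jackknife (Busing et al. 1999) for a scalar estimate.
.jackknife <- function(est, loo, m) {
  B <- length(loo)
  n <- sum(m)
  h <- n / m
  thetaJ <- B * est - sum((1 - m / n) * loo)
  tau <- h * est - (h - 1) * loo
  v <- sum((tau - thetaJ)^2 / (h - 1)) / B
  list(est = thetaJ, se = sqrt(v))
}

## Weighted jackknife covariance for a vector estimate.
## est: length-E vector; loo: B x E matrix; m: length-B block weights.
.jackknifeCov <- function(est, loo, m) {
  B <- nrow(loo)
  n <- sum(m)
  h <- n / m
  thetaJ <- B * est - colSums((1 - m / n) * loo)
  tau <- h * matrix(est, B, length(est), byrow = TRUE) - (h - 1) * loo
  dev <- sweep(tau, 2, thetaJ)
  cv <- crossprod(dev / sqrt(h - 1)) / B
  list(est = thetaJ, cov = cv)
}
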