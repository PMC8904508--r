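## Relatedness screening from pairwise mismatch rates (PMR) of
## pseudo-haploid calls.  E[PMR] = (1 - phi) * B for kinship phi and a
## cohort baseline B equal to the expected mismatch of unrelated pairs
## (~ the population heterozygosity), so duplicates sit near B/2,
## first-degree relatives near 0.75 B and second-degree near 0.875 B.

#' Pairwise mismatch rates between call columns
#'
#' @param x A [CallMatrix-class] (typically pseudo-haploid).
#' @param minOverlap Minimum overlapping SNPs for a pair to be considered
#'   informative; pairs below it are kept but flagged (default 3000, which
#'   keeps the binomial SE of the PMR below ~0.008, small relative to the
#'   0.03-0.06 gaps between relatedness classes).
#' @return A `data.frame` with one row per unordered pair: `indA`, `indB`,
#'   `nOverlap`, `nMismatch`, `pmr`, `se`, `sufficient`.
#' @export
pairwiseMismatch <- function(x, minOverlap = 3000L) {
  stopifnot(is(x, "CallMatrix"))
  m <- calls(x)
  if (ncol(m) < 2) stop("need at least 2 individuals")
  obs <- !is.na(m)
  mm0 <- m; mm0[is.na(mm0)] <- -1L
  ## mismatch count: overlap minus matches, via one crossprod per dosage value
  ov <- crossprod(obs)
  eq <- matrix(0, ncol(m), ncol(m))
  for (v in 0:ploidy(x)) {
    iv <- mm0 == v
    eq <- eq + crossprod(iv)
  }
  mis <- ov - eq
  pairs <- which(upper.tri(ov), arr.ind = TRUE)
  nOv <- ov[pairs]; nMis <- mis[pairs]
  pmr <- ifelse(nOv > 0, nMis / nOv, NA_real_)
  se <- ifelse(nOv > 0, sqrt(pmax(pmr * (1 - pmr), 0) / nOv), NA_real_)
  data.frame(indA = colnames(m)[pairs[, 1]],
             indB = colnames(m)[pairs[, 2]],
             nOverlap = as.integer(nOv), nMismatch = as.integer(nMis),
             pmr = pmr, se = se,
             sufficient = nOv >= minOverlap,
             stringsAsFactors = FALSE)
}

#' Estimate the unrelated-pair PMR baseline
#'
#' Assumes most pairs are unrelated: PMR values are grouped into clusters
#' by splitting the sorted values at gaps larger than `gap`, and the
#' baseline is the median of the largest (modal) cluster.
#'
#' @param pmr A `data.frame` from [pairwiseMismatch()].
#' @param gap Minimum gap between clusters (default 0.03, about half the
#'   smallest class separation at a baseline of 0.24).
#' @return The baseline B (a single number).
#' @export
estimateBaseline <- function(pmr, gap = 0.03) {
  v <- pmr$pmr[pmr$sufficient & !is.na(pmr$pmr)]
  if (length(v) < 3) stop("need at least 3 informative pairs")
  v <- sort(v)
  cl <- cumsum(c(0, diff(v) > gap))
  sizes <- table(cl)
  big <- names(sizes)[sizes == max(sizes)]
  big <- big[length(big)]  # tie -> higher-PMR cluster (unrelated majority)
  median(v[cl == as.integer(big)])
}

#' Classify pairs into relatedness classes from PMR
#'
#' Each pair is assigned the class whose expected PMR `(1 - phi) B`
#' (phi = 1/2, 1/4, 1/8, 0) is nearest, i.e. thresholds at the midpoints
#' `0.625 B`, `0.8125 B`, `0.9375 B`. A pair within 2 SE of two expected
#' values is flagged ambiguous. First-degree subtypes (parent-offspring vs
#' full sibling) are not distinguished here; export genotypes for a
#' likelihood-based IBD tool for that.
#'
#' @param pmr A `data.frame` from [pairwiseMismatch()].
#' @param B Baseline from [estimateBaseline()].
#' @return The input with added columns `class` (one of `duplicate`,
#'   `first_degree`, `second_degree`, `unrelated`) and `ambiguous`.
#' @export
classifyPairs <- function(pmr, B) {
  if (B <= 0 || B >= 1) stop("baseline must lie in (0, 1)")
  expected <- c(duplicate = 0.5, first_degree = 0.75,
                second_degree = 0.875, unrelated = 1) * B
  d <- abs(outer(pmr$pmr, expected, "-"))
  cls <- colnames(d)[max.col(-d, ties.method = "first")]
  near <- d <= 2 * pmr$se  # within 2 SE of an expected value
  amb <- rowSums(near, na.rm = TRUE) >= 2
  pmr$class <- cls
  pmr$class[!pmr$sufficient] <- NA_character_
  pmr$ambiguous <- amb & pmr$sufficient
  pmr
}

#' Heatmap of pairwise mismatch rates
#'
#' @param pmr A `data.frame` from [pairwiseMismatch()].
#' @param ... Passed to [graphics::image()].
#' @return The symmetric PMR matrix, invisibly.
#' @export
plotPmrHeatmap <- function(pmr, ...) {
  ids <- sort(unique(c(pmr$indA, pmr$indB)))
  m <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  m[cbind(pmr$indA, pmr$indB)] <- pmr$pmr
  m[cbind(pmr$indB, pmr$indA)] <- pmr$pmr
  graphics::image(seq_along(ids), seq_along(ids), m, axes = FALSE,
                  xlab = "", ylab = "",
                  col = grDevices::hcl.colors(50, "YlOrRd", rev = TRUE),
                  ...)
  graphics::axis(1, seq_along(ids), ids, las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_along(ids), ids, las = 2, cex.axis = 0.6)
  invisible(m)
}

#' Merge duplicate call columns into per-individual calls
#'
#' When the underlying pileup is available the reads of a duplicate group
#' are pooled and the pseudo-haploid draw repeated, mirroring the merge of
#' per-library data into per-individual data; otherwise the merged call at
#' a site is the consensus of non-missing member calls, with disagreements
#' resolved by a seeded uniform draw.
#'
#' @param x A [CallMatrix-class].
#' @param groups A named list of character vectors; each element lists the
#'   columns of one duplicate group and is replaced by a single column
#'   named after the element. Groups must be disjoint.
#' @param pileup Optional pileup `data.frame` covering the group members.
#' @param ... Passed to [callPseudohaploid()] when `pileup` is given.
#' @param seed Seed for disagreement draws.
#' @return A [CallMatrix-class] with one column per merged group plus all
#'   unmerged columns.
#' @export
mergeDuplicates <- function(x, groups, pileup = NULL, ..., seed = 1L) {
  stopifnot(is(x, "CallMatrix"))
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members)) stop("duplicate groups must be disjoint")
  stopifnot(all(members %in% individuals(x)))
  m <- calls(x)
  s <- snpInfo(x)
  keepCols <- setdiff(colnames(m), members)
  out <- m[, keepCols, drop = FALSE]
  for (gname in names(groups)) {
    g <- groups[[gname]]
    if (is.null(pileup)) {
      sub <- m[, g, drop = FALSE]
      nObs <- rowSums(!is.na(sub))
      val <- rep(NA_integer_, nrow(sub))
      one <- nObs >= 1
      ## uniform draw among the non-missing member calls, per-site stream
      u <- siteUniform(seed, s$chrom, s$pos, gname)
      pickIdx <- floor(u * nObs) + 1L
      obsList <- which(!is.na(sub), arr.ind = TRUE)
      if (nrow(obsList)) {
        ord <- order(obsList[, 1], obsList[, 2])
        obsList <- obsList[ord, , drop = FALSE]
        first <- match(seq_len(nrow(sub)), obsList[, 1])
        sel <- first + pmin(pickIdx - 1L, nObs - 1L)
        has <- one & !is.na(first)
        val[has] <- sub[cbind(obsList[sel[has], 1], obsList[sel[has], 2])]
      }
      val[!one] <- NA_integer_
    } else {
      pp <- pileup[pileup$individual %in% g, , drop = FALSE]
      pp$individual <- gname
      cm <- callPseudohaploid(pp, x@panel, seed = seed, ...)
      val <- calls(cm)[, gname]
    }
    out <- cbind(out, val)
    colnames(out)[ncol(out)] <- gname
  }
  CallMatrix(out, x@panel, ploidy = x@ploidy)
}
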