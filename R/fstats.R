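## f2/f3/f4 moment statistics of allele-frequency differences, with
## small-sample bias corrections (Patterson-style) and weighted block
## jackknife standard errors.

#' Allele counts per population from genotype calls
#'
#' @param x A [CallMatrix-class].
#' @param groups Either a named list (population -> individuals) or a named
#'   character vector (individual -> population).
#' @return An [AlleleCounts-class]: per population and SNP the
#'   alternative-allele count and the number of called alleles (1 per
#'   pseudo-haploid call, 2 per diploid genotype).
#' @export
alleleCounts <- function(x, groups) {
  stopifnot(is(x, "CallMatrix"))
  if (!is.list(groups)) {
    groups <- split(names(groups), unname(groups))
  }
  m <- calls(x)
  pl <- ploidy(x)
  pops <- names(groups)
  xs <- matrix(0, length(pops), nrow(m), dimnames = list(pops, rownames(m)))
  ns <- xs
  for (p in pops) {
    sub <- m[, groups[[p]], drop = FALSE]
    xs[p, ] <- rowSums(sub, na.rm = TRUE)
    ns[p, ] <- pl * rowSums(!is.na(sub))
  }
  new("AlleleCounts", x = xs, n = ns,
      ploidy = setNames(rep(as.integer(pl), length(pops)), pops),
      panel = x@panel)
}

#' Sample allele counts from true population frequencies
#'
#' Binomial sampling of `sizes[pop]` alleles per SNP from a frequency
#' table; used to emulate genotyped reference panels in simulations.
#'
#' @param freqs A [FreqTable-class].
#' @param sizes Named integer vector: alleles sampled per population
#'   (e.g. `2 * individuals` for diploid panels).
#' @param ploidy Recorded ploidy per population (default 2).
#' @param missingRate Per-allele dropout probability: the called total at
#'   a SNP is Binomial(`sizes`, `1 - missingRate`) (default 0).
#' @param seed Integer seed.
#' @return An [AlleleCounts-class].
#' @export
sampleAlleleCounts <- function(freqs, sizes, ploidy = 2L, missingRate = 0,
                               seed = 1L) {
  stopifnot(is(freqs, "FreqTable"), !is.null(names(sizes)))
  pops <- names(sizes)
  stopifnot(all(pops %in% rownames(freqs@freq)))
  nS <- nSnps(freqs)
  xs <- matrix(0, length(pops), nS,
               dimnames = list(pops, colnames(freqs@freq)))
  ns <- xs
  pl <- rep(as.integer(ploidy), length.out = length(pops))
  for (i in seq_along(pops)) {
    p <- pops[i]
    withSeed(subSeed(seed, "counts", p), {
      nCalled <- if (missingRate > 0)
        rbinom(nS, sizes[[p]], 1 - missingRate) else rep(sizes[[p]], nS)
      xs[p, ] <- rbinom(nS, nCalled, freqs@freq[p, ])
      ns[p, ] <- nCalled
    })
  }
  new("AlleleCounts", x = xs, n = ns, ploidy = setNames(pl, pops),
      panel = freqs@panel)
}

#' Combine allele-count tables over the same panel
#' @param ... [AlleleCounts-class] objects sharing a panel.
#' @return A single [AlleleCounts-class] with the union of populations.
#' @export
bindCounts <- function(...) {
  lst <- list(...)
  p <- lst[[1]]@panel
  new("AlleleCounts",
      x = do.call(rbind, lapply(lst, function(a) a@x)),
      n = do.call(rbind, lapply(lst, function(a) a@n)),
      ploidy = do.call(c, lapply(lst, function(a) a@ploidy)),
      panel = p)
}

## per-SNP statistic values plus the contributing-SNP mask
.fstatPerSnp <- function(ac, kind, pops, corrected) {
  X <- ac@x[pops, , drop = FALSE]
  N <- ac@n[pops, , drop = FALSE]
  use <- colSums(N >= 1) == length(pops)
  f <- X / N  # NaN where n = 0; masked below
  if (kind == "f2") {
    a <- f[1, ]; b <- f[2, ]
    v <- (a - b)^2
    if (corrected) {
      use <- use & N[1, ] >= 2 & N[2, ] >= 2
      v <- v - a * (1 - a) / (N[1, ] - 1) - b * (1 - b) / (N[2, ] - 1)
    }
  } else if (kind == "f3") {
    cc <- f[1, ]; a <- f[2, ]; b <- f[3, ]
    v <- (cc - a) * (cc - b)
    if (corrected) {
      use <- use & N[1, ] >= 2
      v <- v - cc * (1 - cc) / (N[1, ] - 1)
    }
  } else {
    v <- (f[1, ] - f[2, ]) * (f[3, ] - f[4, ])
  }
  v[!use] <- NA_real_
  list(values = v, use = use)
}

.fstatResult <- function(kind, pops, per, blocks, details, w = NULL) {
  if (!any(per$use)) stop("no overlapping SNPs for ", kind)
  wu <- if (is.null(w)) rep(1, sum(per$use)) else w[per$use]
  if (is.null(blocks)) {
    est <- sum(per$values[per$use] * wu) / sum(wu)
    res <- new("FStatResult", statistic = kind, pops = pops,
               estimate = est, se = NA_real_, z = NA_real_,
               nSnps = sum(per$use), nBlocks = 0L,
               blockSums = numeric(0), blockCounts = numeric(0))
  } else {
    jk <- blockJackknife(per$values[per$use], blocks[per$use], weights = wu)
    res <- new("FStatResult", statistic = kind, pops = pops,
               estimate = jk$estimate, se = jk$se,
               z = jk$estimate / jk$se, nSnps = sum(per$use),
               nBlocks = length(jk$blockSums),
               blockSums = jk$blockSums, blockCounts = jk$blockCounts)
  }
  if (details) list(result = res, perSnp = per$values, use = per$use)
  else res
}

## per-SNP weights: 1 (plain mean) or the harmonic mean of the argument
## populations' called-allele counts (ratio-of-sums-style aggregation that
## down-weights poorly covered SNPs)
.fstatWeights <- function(ac, pops, aggregation) {
  if (aggregation == "mean") return(NULL)
  N <- ac@n[pops, , drop = FALSE]
  k <- length(pops)
  w <- k / colSums(1 / pmax(N, 1e-12))
  w[colSums(N >= 1) < k] <- 0
  w
}

#' f2, f3 and f4 statistics
#'
#' Per-SNP definitions with sample frequencies `a = x/n` etc.:
#' * `f2(A, B)`: `(a - b)^2`, minus the bias correction
#'   `a(1-a)/(nA - 1) + b(1-b)/(nB - 1)` when `corrected`.
#' * `f3(C; A, B)`: `(c - a)(c - b)` minus `c(1-c)/(nC - 1)` when
#'   `corrected`. The correction is disabled automatically (with a
#'   message) when the target population was genotyped pseudo-haploid,
#'   where the within-individual binomial model behind it does not hold.
#' * `f4(A, B; C, D)`: `(a - b)(c - d)`; no correction needed.
#'
#' A SNP contributes when all argument populations have `n >= 1`
#' (`n >= 2` where a correction divides by `n - 1`). By default the
#' aggregate is the unweighted mean over contributing SNPs;
#' `aggregation = "weighted"` instead weights each SNP by the harmonic
#' mean of the argument populations' called-allele counts, a
#' ratio-of-sums-style aggregation that down-weights poorly covered
#' SNPs. Standard errors come from the weighted block jackknife when
#' `blocks` is supplied.
#'
#' @param ac An [AlleleCounts-class].
#' @param A,B,C,D Population names.
#' @param corrected Apply small-sample bias corrections.
#' @param blocks Block ids from [assignBlocks()] (length = panel SNPs);
#'   `NULL` for a point estimate without SE.
#' @param aggregation `"mean"` (default) or `"weighted"`; see Details.
#' @param details If `TRUE`, also return the per-SNP vector and mask.
#' @return An [FStatResult-class] (or a list when `details = TRUE`).
#' @export
f2 <- function(ac, A, B, corrected = TRUE, blocks = NULL,
               aggregation = c("mean", "weighted"), details = FALSE) {
  aggregation <- match.arg(aggregation)
  per <- .fstatPerSnp(ac, "f2", c(A, B), corrected)
  .fstatResult("f2", c(A, B), per, blocks, details,
               w = .fstatWeights(ac, c(A, B), aggregation))
}

#' @rdname f2
#' @export
f3 <- function(ac, C, A, B, corrected = TRUE, blocks = NULL,
               aggregation = c("mean", "weighted"), details = FALSE) {
  aggregation <- match.arg(aggregation)
  if (corrected && ac@ploidy[[C]] == 1L) {
    message("target population ", C,
            " is pseudo-haploid; disabling the f3 bias correction")
    corrected <- FALSE
  }
  if (all(ac@n[C, ] == 0)) stop("target population has no called alleles")
  per <- .fstatPerSnp(ac, "f3", c(C, A, B), corrected)
  .fstatResult("f3", c(C, A, B), per, blocks, details,
               w = .fstatWeights(ac, c(C, A, B), aggregation))
}

#' @rdname f2
#' @export
f4 <- function(ac, A, B, C, D, blocks = NULL,
               aggregation = c("mean", "weighted"), details = FALSE) {
  aggregation <- match.arg(aggregation)
  per <- .fstatPerSnp(ac, "f4", c(A, B, C, D), corrected = FALSE)
  .fstatResult("f4", c(A, B, C, D), per, blocks, details,
               w = .fstatWeights(ac, c(A, B, C, D), aggregation))
}

#' Batch f-statistics over population lists
#'
#' @param ac An [AlleleCounts-class].
#' @param pops A `data.frame` (or matrix) whose rows give the population
#'   arguments, 2 columns for f2, 3 for f3 (target first), 4 for f4 —
#'   or the path of a whitespace-delimited population-list file with the
#'   same layout (one statistic per line, `#` comments allowed).
#' @param statistic "f2", "f3" or "f4".
#' @param blocks Block ids (see [assignBlocks()]).
#' @param corrected Bias correction where applicable.
#' @return A `data.frame` with estimate, SE, z, nSnps, nBlocks per row.
#' @export
fstatBatch <- function(ac, pops, statistic = c("f3", "f2", "f4"),
                       blocks = NULL, corrected = TRUE) {
  statistic <- match.arg(statistic)
  if (is.character(pops) && length(pops) == 1 && file.exists(pops))
    pops <- as.matrix(read.table(pops, header = FALSE,
                                 comment.char = "#"))
  pops <- as.matrix(pops)
  out <- lapply(seq_len(nrow(pops)), function(i) {
    r <- switch(statistic,
      f2 = f2(ac, pops[i, 1], pops[i, 2], corrected, blocks),
      f3 = suppressMessages(
        f3(ac, pops[i, 1], pops[i, 2], pops[i, 3], corrected, blocks)),
      f4 = f4(ac, pops[i, 1], pops[i, 2], pops[i, 3], pops[i, 4], blocks))
    data.frame(statistic = statistic,
               pops = paste(pops[i, ], collapse = ","),
               estimate = r@estimate, se = r@se, z = r@z,
               nSnps = r@nSnps, nBlocks = r@nBlocks)
  })
  do.call(rbind, out)
}
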