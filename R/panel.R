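#' Construct a SNPPanel
#'
#' @param chrom Chromosome identifiers (coerced to character).
#' @param pos 1-based physical positions in bp.
#' @param ref,alt Reference / alternative alleles ("A", "C", "G", "T").
#' @param gpos Genetic positions in Morgans. When `NULL`, positions are
#'   interpolated at the default uniform rate of 1 cM per Mb.
#' @param id SNP identifiers; autogenerated when `NULL`.
#' @return A [SNPPanel-class], sorted by (chromosome, position).
#' @export
#' @examples
#' p <- SNPPanel(chrom = "1", pos = c(100, 200), ref = c("A", "C"),
#'               alt = c("G", "G"))
#' nSnps(p)
SNPPanel <- function(chrom, pos, ref, alt, gpos = NULL, id = NULL) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (is.null(gpos)) gpos <- pos * 1e-8  # 1 cM/Mb in Morgans
  if (is.null(id)) id <- sprintf("snp_%s_%d", chrom, pos)
  amb <- (ref == "A" & alt == "T") | (ref == "T" & alt == "A") |
         (ref == "C" & alt == "G") | (ref == "G" & alt == "C")
  s <- data.frame(id = id, chrom = chrom, pos = pos, gpos = gpos,
                  ref = ref, alt = alt, ambiguous = amb,
                  stringsAsFactors = FALSE)
  s <- s[order(s$chrom, s$pos), , drop = FALSE]
  rownames(s) <- NULL
  new("SNPPanel", snps = s)
}

#' Simulate a random SNPPanel
#'
#' Draws SNP positions uniformly along each chromosome with a uniform
#' genetic map of 1 cM per Mb, and random non-identical alleles.
#'
#' @param nSnps Total number of SNPs.
#' @param nChrom Number of chromosomes (named "1", "2", ...).
#' @param chromLengthMb Chromosome length in Mb.
#' @param seed Integer seed.
#' @param alleles Optional length-2 character fixing `c(ref, alt)` at every
#'   SNP (e.g. `c("C", "T")` for deamination fixtures).
#' @param dropAmbiguous Drop strand-ambiguous allele draws (default TRUE).
#' @return A [SNPPanel-class].
#' @export
simulatePanel <- function(nSnps, nChrom = 1L, chromLengthMb = 100,
                          seed = 1L, alleles = NULL, dropAmbiguous = TRUE) {
  withSeed(subSeed(seed, "panel"), {
    per <- rep(nSnps %/% nChrom, nChrom)
    if (nSnps %% nChrom) per[seq_len(nSnps %% nChrom)] <- per[seq_len(nSnps %% nChrom)] + 1L
    chrom <- rep(as.character(seq_len(nChrom)), per)
    pos <- unlist(lapply(per, function(k)
      sort(sample.int(as.integer(chromLengthMb * 1e6), k))))
    n <- length(pos)
    if (is.null(alleles)) {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, n, replace = TRUE)
      alt <- character(n)
      for (b in bases) {
        allowed <- setdiff(bases, if (dropAmbiguous) c(b, comp[[b]]) else b)
        idx <- which(ref == b)
        alt[idx] <- sample(allowed, length(idx), replace = TRUE)
      }
    } else {
      ref <- rep(alleles[1], n)
      alt <- rep(alleles[2], n)
    }
    SNPPanel(chrom = chrom, pos = pos, ref = ref, alt = alt)
  })
}

#' @rdname adnapipe-generics
#' @export
setMethod("nSnps", "SNPPanel", function(x) nrow(x@snps))

#' @rdname adnapipe-generics
#' @export
setMethod("snpInfo", "SNPPanel", function(x) x@snps)

#' @export
setMethod("show", "SNPPanel", function(object) {
  s <- object@snps
  cat(sprintf("SNPPanel: %d SNPs on %d chromosome(s); %d strand-ambiguous\n",
              nrow(s), length(unique(s$chrom)), sum(s$ambiguous)))
})

#' Subset a SNPPanel by SNP index
#' @param x A [SNPPanel-class].
#' @param i Integer or logical index over SNPs.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "SNPPanel", function(x, i, j, ..., drop = FALSE) {
  s <- x@snps[i, , drop = FALSE]
  rownames(s) <- NULL
  new("SNPPanel", snps = s)
})

#' Construct a CallMatrix
#'
#' @param calls SNPs x individuals matrix of alt-allele dosages (NA missing).
#' @param panel The [SNPPanel-class].
#' @param ploidy 1 for pseudo-haploid, 2 for diploid.
#' @return A [CallMatrix-class].
#' @export
CallMatrix <- function(calls, panel, ploidy = 1L) {
  storage.mode(calls) <- "integer"
  new("CallMatrix", calls = calls, panel = panel, ploidy = as.integer(ploidy))
}

#' @rdname adnapipe-generics
#' @export
setMethod("calls", "CallMatrix", function(x) x@calls)

#' @rdname adnapipe-generics
#' @export
setMethod("ploidy", "CallMatrix", function(x) x@ploidy)

#' @rdname adnapipe-generics
#' @export
setMethod("individuals", "CallMatrix", function(x) colnames(x@calls))

#' @rdname adnapipe-generics
#' @export
setMethod("nSnps", "CallMatrix", function(x) nrow(x@calls))

#' @rdname adnapipe-generics
#' @export
setMethod("snpInfo", "CallMatrix", function(x) x@panel@snps)

#' @export
setMethod("show", "CallMatrix", function(object) {
  m <- object@calls
  miss <- mean(is.na(m))
  cat(sprintf("CallMatrix: %d SNPs x %d individuals (ploidy %d), %.1f%% missing\n",
              nrow(m), ncol(m), object@ploidy, 100 * miss))
})

#' @rdname adnapipe-generics
#' @export
setMethod("freq", "FreqTable", function(x) x@freq)

#' @rdname adnapipe-generics
#' @export
setMethod("populations", "FreqTable", function(x) rownames(x@freq))

#' @rdname adnapipe-generics
#' @export
setMethod("nSnps", "FreqTable", function(x) ncol(x@freq))

#' @rdname adnapipe-generics
#' @export
setMethod("snpInfo", "FreqTable", function(x) x@panel@snps)

#' @export
setMethod("show", "FreqTable", function(object) {
  cat(sprintf("FreqTable: %d populations x %d SNPs (root Beta(%.3g, %.3g), %d clipped draws)\n",
              nrow(object@freq), ncol(object@freq),
              object@rootShape[1], object@rootShape[2], object@clipped))
})

#' @rdname adnapipe-generics
#' @export
setMethod("populations", "AlleleCounts", function(x) rownames(x@x))

#' @rdname adnapipe-generics
#' @export
setMethod("nSnps", "AlleleCounts", function(x) ncol(x@x))

#' @rdname adnapipe-generics
#' @export
setMethod("ploidy", "AlleleCounts", function(x) x@ploidy)

#' @rdname adnapipe-generics
#' @export
setMethod("snpInfo", "AlleleCounts", function(x) x@panel@snps)

#' @export
setMethod("show", "AlleleCounts", function(object) {
  cat(sprintf("AlleleCounts: %d populations x %d SNPs\n",
              nrow(object@x), ncol(object@x)))
})

#' @export
setMethod("show", "FStatResult", function(object) {
  cat(sprintf("%s(%s) = %.6g  SE %.3g  z %.2f  (%d SNPs, %d blocks)\n",
              object@statistic, paste(object@pops, collapse = ", "),
              object@estimate, object@se, object@z,
              object@nSnps, object@nBlocks))
})
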