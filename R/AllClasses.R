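## Central S4 data containers shared by all pipeline stages.

#' SNPPanel: the marker list shared by all stages
#'
#' Holds one row per biallelic SNP: chromosome, physical position (1-based
#' bp), genetic position (Morgans), reference and alternative allele, and a
#' flag for strand-ambiguous (A/T or C/G) sites. Rows are kept sorted by
#' (chromosome, position) and genetic positions are non-decreasing within a
#' chromosome.
#'
#' @slot snps A `data.frame` with columns `id`, `chrom`, `pos`, `gpos`,
#'   `ref`, `alt`, `ambiguous`.
#' @export
setClass("SNPPanel", slots = c(snps = "data.frame"))

setValidity("SNPPanel", function(object) {
  s <- object@snps
  need <- c("id", "chrom", "pos", "gpos", "ref", "alt", "ambiguous")
  if (!all(need %in% names(s)))
    return(paste("missing columns:", paste(setdiff(need, names(s)), collapse = ", ")))
  if (nrow(s) == 0) return(TRUE)
  if (any(s$ref == s$alt)) return("ref allele equals alt allele")
  if (!all(c(s$ref, s$alt) %in% c("A", "C", "G", "T")))
    return("alleles must be A/C/G/T")
  o <- order(s$chrom, s$pos)
  if (!all(o == seq_len(nrow(s)))) return("SNPs not sorted by (chromosome, position)")
  bad <- tapply(s$gpos, s$chrom, function(g) any(diff(g) < 0))
  if (any(unlist(bad))) return("genetic positions decrease within a chromosome")
  TRUE
})

#' CallMatrix: genotype calls over a SNPPanel
#'
#' A SNPs x individuals integer matrix of alternative-allele dosages.
#' Pseudo-haploid calls (`ploidy = 1`) take values in \{0, 1, NA\}; diploid
#' genotypes (`ploidy = 2`) in \{0, 1, 2, NA\}. `NA` is missing.
#'
#' @slot calls Integer matrix, SNPs in rows, individuals in columns.
#' @slot panel The [SNPPanel-class] the rows refer to.
#' @slot ploidy Integer, 1 (pseudo-haploid) or 2 (diploid).
#' @export
setClass("CallMatrix",
         slots = c(calls = "matrix", panel = "SNPPanel", ploidy = "integer"))

setValidity("CallMatrix", function(object) {
  if (nrow(object@calls) != nSnps(object@panel))
    return("call matrix rows do not match panel size")
  if (!object@ploidy %in% c(1L, 2L)) return("ploidy must be 1 or 2")
  v <- object@calls
  ok <- is.na(v) | (v >= 0L & v <= object@ploidy)
  if (!all(ok)) return("calls outside {0..ploidy, NA}")
  if (is.null(colnames(object@calls))) return("individuals must be named")
  TRUE
})

#' FreqTable: population allele frequencies over a SNPPanel
#'
#' Populations (graph nodes) in rows, SNPs in columns, alternative-allele
#' frequencies in `[0, 1]`. Carries the root Beta shape parameters used by
#' the simulator and a count of draws truncated at the `{0, 1}` boundary.
#'
#' @slot freq Numeric matrix, populations x SNPs.
#' @slot panel The [SNPPanel-class].
#' @slot rootShape Numeric length-2: Beta(a, b) shape of root frequencies.
#' @slot clipped Integer: number of frequency draws truncated at 0/1.
#' @export
setClass("FreqTable",
         slots = c(freq = "matrix", panel = "SNPPanel",
                   rootShape = "numeric", clipped = "integer"))

setValidity("FreqTable", function(object) {
  f <- object@freq
  if (ncol(f) != nSnps(object@panel)) return("freq columns do not match panel")
  if (any(f < 0 | f > 1)) return("frequencies outside [0, 1]")
  if (is.null(rownames(f))) return("populations must be named")
  TRUE
})

#' AlleleCounts: per-population derived-allele counts
#'
#' For every population and SNP, the count `x` of alternative alleles among
#' `n` called alleles (haploid calls contribute 1, diploid genotypes 2).
#' The `ploidy` vector records how each population was genotyped, which
#' controls whether small-sample bias corrections are applicable.
#'
#' @slot x Numeric matrix (populations x SNPs) of alt-allele counts.
#' @slot n Numeric matrix of total called alleles.
#' @slot ploidy Named integer vector per population (1 or 2).
#' @slot panel The [SNPPanel-class].
#' @export
setClass("AlleleCounts",
         slots = c(x = "matrix", n = "matrix", ploidy = "integer",
                   panel = "SNPPanel"))

setValidity("AlleleCounts", function(object) {
  if (!identical(dim(object@x), dim(object@n))) return("x/n dimension mismatch")
  if (ncol(object@x) != nSnps(object@panel)) return("columns do not match panel")
  if (any(object@n < 0)) return("negative n")
  if (any(object@x < 0 | object@x > object@n)) return("x outside [0, n]")
  if (is.null(rownames(object@x))) return("populations must be named")
  TRUE
})

#' AdmixtureGraph: drift topology with admixture nodes
#'
#' A rooted directed acyclic graph. Every edge carries a drift length
#' `c >= 0`; an admixture node has exactly two incoming edges and a mixing
#' weight `alpha` giving the contribution of its first parent. Non-admixture,
#' non-root nodes have exactly one parent.
#'
#' @slot edges `data.frame` with columns `parent`, `child`, `drift`.
#' @slot admixture `data.frame` with columns `child`, `parentA`, `parentB`,
#'   `alpha`; `alpha` is the weight on `parentA`.
#' @export
setClass("AdmixtureGraph",
         slots = c(edges = "data.frame", admixture = "data.frame"))

setValidity("AdmixtureGraph", function(object) {
  e <- object@edges; a <- object@admixture
  if (!all(c("parent", "child", "drift") %in% names(e)))
    return("edges need parent/child/drift")
  if (!all(c("child", "parentA", "parentB", "alpha") %in% names(a)))
    return("admixture needs child/parentA/parentB/alpha")
  if (any(e$drift < 0)) return("drift lengths must be >= 0")
  if (nrow(a) && any(a$alpha < 0 | a$alpha > 1)) return("alpha outside [0, 1]")
  nodes <- union(e$parent, e$child)
  roots <- setdiff(e$parent, e$child)
  if (length(roots) != 1) return(sprintf("graph must have exactly one root (found %d)", length(roots)))
  ## in-degree: 1 for plain nodes, 2 for admixture nodes
  indeg <- table(e$child)
  adm <- a$child
  for (nd in names(indeg)) {
    k <- indeg[[nd]]
    if (nd %in% adm && k != 2) return(sprintf("admixture node %s must have 2 parents", nd))
    if (!(nd %in% adm) && k != 1) return(sprintf("node %s has %d parents but is not an admixture node", nd, k))
  }
  if (nrow(a)) {
    for (i in seq_len(nrow(a))) {
      pp <- sort(c(a$parentA[i], a$parentB[i]))
      ee <- sort(e$parent[e$child == a$child[i]])
      if (!identical(pp, ee)) return(sprintf("admixture parents of %s do not match edges", a$child[i]))
    }
  }
  if (is.null(.topoOrder(e))) return("graph contains a cycle")
  TRUE
})

#' FStatResult: a single f-statistic with block-jackknife uncertainty
#'
#' @slot statistic Character, one of "f2", "f3", "f4".
#' @slot pops Character vector of population arguments, in order.
#' @slot estimate Mean of the per-SNP statistic over contributing SNPs.
#' @slot se Weighted block-jackknife standard error.
#' @slot z `estimate / se`.
#' @slot nSnps Number of contributing SNPs.
#' @slot nBlocks Number of jackknife blocks.
#' @slot blockSums Per-block sums of the per-SNP statistic.
#' @slot blockCounts Per-block contributing-SNP counts.
#' @export
setClass("FStatResult",
         slots = c(statistic = "character", pops = "character",
                   estimate = "numeric", se = "numeric", z = "numeric",
                   nSnps = "integer", nBlocks = "integer",
                   blockSums = "numeric", blockCounts = "numeric"))

## topological order of nodes, or NULL on a cycle
.topoOrder <- function(edges) {
  nodes <- union(edges$parent, edges$child)
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(edges$child)
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  avail <- names(indeg)[indeg == 0L]
  indeg <- indeg
  rem <- edges
  while (length(avail)) {
    nd <- sort(avail)[1]
    avail <- setdiff(avail, nd)
    out <- c(out, nd)
    ch <- rem$child[rem$parent == nd]
    rem <- rem[rem$parent != nd, , drop = FALSE]
    for (cnd in ch) {
      indeg[cnd] <- indeg[cnd] - 1L
      if (indeg[cnd] == 0L) avail <- c(avail, cnd)
    }
  }
  if (length(out) != length(nodes)) NULL else out
}
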