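#' Merge genotype datasets on shared SNPs
#'
#' Datasets are intersected on (chromosome, position). Allele pairs must
#' match, allowing a ref/alt swap which is harmonized by flipping dosages
#' (`call -> ploidy - call`). Strand-ambiguous (A/T, C/G) sites are removed
#' when `dropStrandAmbiguous` is set, since their orientation cannot be
#' verified across genotyping platforms. Sites with irreconcilable allele
#' pairs are dropped and counted.
#'
#' @param datasets A list of [CallMatrix-class] objects.
#' @param dropStrandAmbiguous Remove A/T and C/G SNPs (default TRUE).
#' @return A list with `datasets` (the harmonized [CallMatrix-class]
#'   objects sharing one panel), `panel`, and `log` (counts of dropped
#'   sites by reason).
#' @export
mergePanels <- function(datasets, dropStrandAmbiguous = TRUE) {
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, function(d) is(d, "CallMatrix"), TRUE)))
  keys <- lapply(datasets, function(d) {
    s <- snpInfo(d); paste(s$chrom, s$pos)
  })
  shared <- Reduce(intersect, keys)
  ref <- datasets[[1]]
  s1 <- snpInfo(ref)
  i1 <- match(shared, keys[[1]])
  flipped <- irreconcilable <- logical(length(shared))
  flips <- vector("list", length(datasets))
  flips[[1]] <- rep(FALSE, length(shared))
  idx <- vector("list", length(datasets))
  idx[[1]] <- i1
  for (k in seq_along(datasets)[-1]) {
    sk <- snpInfo(datasets[[k]])
    ik <- match(shared, keys[[k]])
    same <- sk$ref[ik] == s1$ref[i1] & sk$alt[ik] == s1$alt[i1]
    swap <- sk$ref[ik] == s1$alt[i1] & sk$alt[ik] == s1$ref[i1]
    irreconcilable <- irreconcilable | (!same & !swap)
    flips[[k]] <- swap
    idx[[k]] <- ik
  }
  keep <- !irreconcilable
  if (dropStrandAmbiguous) keep <- keep & !s1$ambiguous[i1]
  nAmb <- sum(!irreconcilable & s1$ambiguous[i1])
  panel <- ref@panel[i1[keep]]
  outSets <- vector("list", length(datasets))
  names(outSets) <- names(datasets)
  for (k in seq_along(datasets)) {
    m <- calls(datasets[[k]])[idx[[k]][keep], , drop = FALSE]
    fl <- flips[[k]][keep]
    pl <- datasets[[k]]@ploidy
    m[fl, ] <- pl - m[fl, , drop = FALSE]
    rownames(m) <- snpInfo(panel)$id
    outSets[[k]] <- CallMatrix(m, panel, ploidy = pl)
  }
  list(datasets = outSets, panel = panel,
       log = list(shared = length(shared),
                  strand_ambiguous_removed = if (dropStrandAmbiguous) nAmb else 0L,
                  irreconcilable_dropped = sum(irreconcilable),
                  kept = sum(keep)))
}
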