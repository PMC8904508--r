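#' Pseudo-haploid genotype calling from a read pileup
#'
#' At every panel site and individual, one eligible read is drawn uniformly
#' at random (with a per-site random stream, see Details) and its base is
#' reported as a haploid call: 0 for the reference allele, 1 for the
#' alternative. A read is eligible when its base quality and mapping
#' quality meet the thresholds, its base is within the read by more than
#' `endTrim` positions from either end, and its base matches one of the
#' site's two alleles. In `single_strand` mode -- appropriate for
#' single-stranded ancient-DNA libraries whose deamination creates C-to-T
#' (and, in reference orientation, G-to-A) errors -- only minus-strand
#' reads are eligible at C/T SNPs and only plus-strand reads at G/A SNPs,
#' which removes damage-driven calls at those sites. Sites with no
#' eligible read are missing.
#'
#' The random draw for a site is keyed by `(seed, chromosome, position,
#' column)` and the eligible reads are put in a canonical order first, so
#' calls do not depend on the row order of the pileup and are stable under
#' subsetting to other sites.
#'
#' @param pileup A pileup `data.frame` (see [simulatePileup()] /
#'   [readPileupTable()] for the columns).
#' @param panel The [SNPPanel-class].
#' @param mode `"double_strand"` (default) or `"single_strand"`; a single
#'   value applied to all reads. Library-specific behaviour is obtained by
#'   calling once per library type.
#' @param minBaseQuality,minMapQuality Phred thresholds (default 30).
#' @param endTrim Bases ignored at each read end (default 5).
#' @param byLibrary If `TRUE`, one call column per library (used for
#'   duplicate detection); otherwise reads are pooled per individual before
#'   the draw.
#' @param seed Integer seed for the per-site draws.
#' @return A pseudo-haploid [CallMatrix-class] with one column per
#'   individual (or library). The attribute `skipped` counts pileup rows at
#'   positions absent from the panel.
#' @export
callPseudohaploid <- function(pileup, panel, mode = "double_strand",
                              minBaseQuality = 30L, minMapQuality = 30L,
                              endTrim = 5L, byLibrary = FALSE, seed = 1L) {
  if (!mode %in% c("double_strand", "single_strand"))
    stop("unknown mode: ", mode)
  s <- snpInfo(panel)
  key <- match(paste(pileup$chrom, pileup$position),
               paste(s$chrom, s$pos))
  skipped <- sum(is.na(key))
  if (skipped > 0)
    warning(sprintf("%d pileup rows at positions absent from the panel were skipped",
                    skipped))
  ok <- !is.na(key)
  p <- pileup[ok, , drop = FALSE]
  site <- key[ok]

  elig <- p$base_quality >= minBaseQuality &
          p$mapping_quality >= minMapQuality &
          p$read_position > endTrim &
          p$read_position <= p$read_length - endTrim &
          (p$base == s$ref[site] | p$base == s$alt[site])
  if (mode == "single_strand") {
    pairKey <- paste0(pmin(s$ref, s$alt)[site], pmax(s$ref, s$alt)[site])
    ct <- pairKey == "CT"
    ga <- pairKey == "AG"
    elig <- elig & !(ct & p$strand != "-") & !(ga & p$strand != "+")
  }
  p <- p[elig, , drop = FALSE]
  site <- site[elig]
  column <- if (byLibrary) p$library else p$individual

  cols <- sort(unique(if (byLibrary) pileup$library else pileup$individual))
  m <- matrix(NA_integer_, nrow = nrow(s), ncol = length(cols),
              dimnames = list(s$id, cols))
  if (nrow(p)) {
    ## canonical order, then one seeded uniform draw per (column, site)
    o <- order(column, site, p$library, p$strand, p$read_position,
               p$base, p$base_quality, p$mapping_quality)
    p <- p[o, , drop = FALSE]
    site <- site[o]
    column <- column[o]
    grp <- cumsum(!duplicated(data.frame(column, site)))
    start <- which(!duplicated(grp))
    len <- diff(c(start, length(grp) + 1L))
    u <- siteUniform(seed, s$chrom[site[start]], s$pos[site[start]],
                     column[start])
    pick <- start + pmin(len - 1L, floor(u * len))
    callVal <- as.integer(p$base[pick] == s$alt[site[pick]])
    m[cbind(site[pick], match(column[pick], cols))] <- callVal
  }
  out <- CallMatrix(m, panel, ploidy = 1L)
  attr(out, "skipped") <- skipped
  out
}
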