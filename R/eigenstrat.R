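## EIGENSTRAT trio (.geno/.snp/.ind) and pileup TSV readers/writers.
## Layout: .geno has one line per SNP with one character per individual
## giving the count of the REFERENCE allele (9 = missing); .snp has
## fixed-width columns id, chrom, genetic position (Morgans), physical
## position, ref, alt; .ind has individual, sex, group.

#' Write a dataset as EIGENSTRAT .geno/.snp/.ind
#'
#' The `.geno` character at a site is the reference-allele count,
#' `ploidy - altDosage` (9 for missing), so a pseudo-haploid matrix uses
#' `{0, 1, 9}` and a diploid one `{0, 1, 2, 9}`. A sidecar `<prefix>.log`
#' records basic counts.
#'
#' @param x A [CallMatrix-class].
#' @param prefix Output path prefix.
#' @param groups Optional named vector mapping individual to group label
#'   (defaults to the individual name).
#' @return `prefix`, invisibly.
#' @export
writeEigenstrat <- function(x, prefix, groups = NULL) {
  stopifnot(is(x, "CallMatrix"))
  s <- snpInfo(x)
  m <- calls(x)
  g <- x@ploidy - m
  g[is.na(g)] <- 9L
  lines <- do.call(paste0, as.data.frame(g))
  writeLines(lines, paste0(prefix, ".geno"))
  snpLines <- sprintf("%20s %4s %15.10f %15d %1s %1s",
                      s$id, s$chrom, s$gpos, s$pos, s$ref, s$alt)
  writeLines(snpLines, paste0(prefix, ".snp"))
  inds <- colnames(m)
  if (is.null(groups)) groups <- setNames(inds, inds)
  indLines <- sprintf("%20s U %s", inds, groups[inds])
  writeLines(indLines, paste0(prefix, ".ind"))
  writeLines(c(sprintf("snps\t%d", nrow(m)),
               sprintf("individuals\t%d", ncol(m)),
               sprintf("missing_calls\t%d", sum(is.na(m))),
               sprintf("ploidy\t%d", x@ploidy)),
             paste0(prefix, ".log"))
  invisible(prefix)
}

#' Read an EIGENSTRAT .geno/.snp/.ind trio
#'
#' @param prefix Path prefix of the three files.
#' @param ploidy Ploidy under which `.geno` values are interpreted
#'   (2 by default; use 1 for pseudo-haploid data written by this package).
#' @return A list with elements `calls` (a [CallMatrix-class]), `panel`
#'   and `ind` (a `data.frame` of individual, sex, group).
#' @export
readEigenstrat <- function(prefix, ploidy = 2L) {
  snp <- read.table(paste0(prefix, ".snp"), header = FALSE,
                    col.names = c("id", "chrom", "gpos", "pos", "ref", "alt"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  ind <- read.table(paste0(prefix, ".ind"), header = FALSE,
                    col.names = c("individual", "sex", "group"),
                    colClasses = "character")
  lines <- readLines(paste0(prefix, ".geno"))
  if (length(lines) != nrow(snp))
    stop(sprintf(".geno has %d lines but .snp has %d SNPs",
                 length(lines), nrow(snp)))
  wid <- nchar(lines)
  if (any(wid != nrow(ind))) {
    bad <- which(wid != nrow(ind))[1]
    stop(sprintf("ragged .geno line %d: %d characters, expected %d",
                 bad, wid[bad], nrow(ind)))
  }
  g <- matrix(as.integer(unlist(strsplit(lines, ""), use.names = FALSE)),
              nrow = nrow(snp), ncol = nrow(ind), byrow = TRUE)
  g[g == 9L] <- NA_integer_
  alt <- as.integer(ploidy) - g
  colnames(alt) <- ind$individual
  panel <- SNPPanel(chrom = snp$chrom, pos = snp$pos, ref = snp$ref,
                    alt = snp$alt, gpos = snp$gpos, id = snp$id)
  ## reorder calls to the panel's canonical (chrom, pos) sort
  key <- order(snp$chrom, snp$pos)
  alt <- alt[key, , drop = FALSE]
  rownames(alt) <- snpInfo(panel)$id
  list(calls = CallMatrix(alt, panel, ploidy = as.integer(ploidy)),
       panel = panel, ind = ind)
}

#' Read / write a pileup table as TSV
#'
#' Columns: individual, library, chrom, position, base, base_quality,
#' mapping_quality, strand, read_position, read_length, library_type.
#'
#' @param pileup A pileup `data.frame`.
#' @param path File path.
#' @export
writePileupTable <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePileupTable
#' @export
readPileupTable <- function(path) {
  p <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c(individual = "character",
                                 library = "character", chrom = "character",
                                 position = "integer", base = "character",
                                 base_quality = "integer",
                                 mapping_quality = "integer",
                                 strand = "character",
                                 read_position = "integer",
                                 read_length = "integer",
                                 library_type = "character"))
  validatePileup(p)
  p
}

#' Validate pileup table invariants
#'
#' Checks bases, non-negative qualities and read positions within the read.
#' @param pileup A pileup `data.frame`.
#' @return The pileup, invisibly; errors on violation.
#' @export
validatePileup <- function(pileup) {
  stopifnot(all(pileup$base %in% c("A", "C", "G", "T")),
            all(pileup$base_quality >= 0),
            all(pileup$mapping_quality >= 0),
            all(pileup$strand %in% c("+", "-")),
            all(pileup$read_position >= 1),
            all(pileup$read_position <= pileup$read_length))
  invisible(pileup)
}

#' Read BED intervals
#'
#' Reads a BED file (0-based, half-open) via `rtracklayer` and converts to
#' 1-based inclusive intervals.
#'
#' @param path BED file path.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`
#'   (1-based inclusive coordinates).
#' @export
readBedIntervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  nm <- gr$name
  df$name <- if (is.null(nm)) sprintf("iv%d", seq_len(nrow(df))) else nm
  df
}
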