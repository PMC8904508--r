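## Y-chromosome haplogroup assignment from ancestral/derived read counts
## at branch-defining markers on a user-supplied tree (marker panels such
## as the public Y trees are inputs, not bundled).

#' Read a marker tree from TSV
#'
#' Columns: `branch`, `parent` (empty or "root" for the root branch),
#' `chrom`, `site` (1-based position), `ancestral`, `derived`.
#' Marker sites must be unique.
#'
#' @param path TSV file path.
#' @return A list of class `markerTree` with `branches` (branch ->
#'   parent) and `markers` (`data.frame`).
#' @export
readMarkerTree <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c(branch = "character", parent = "character",
                                 chrom = "character", site = "integer",
                                 ancestral = "character",
                                 derived = "character"))
  markerTree(m)
}

#' @param markers A `data.frame` with the columns listed above.
#' @rdname readMarkerTree
#' @export
markerTree <- function(markers) {
  if (anyDuplicated(paste(markers$chrom, markers$site)))
    stop("marker sites must be unique")
  br <- unique(markers[, c("branch", "parent")])
  if (anyDuplicated(br$branch)) stop("a branch has two different parents")
  parent <- setNames(br$parent, br$branch)
  parent[parent == ""] <- "root"
  roots <- br$branch[!(parent[br$branch] %in% br$branch)]
  if (!length(roots)) stop("marker tree has no root branch")
  ## cycle check: walk each branch to the root
  for (b in br$branch) {
    seen <- character(0); cur <- b
    while (cur %in% names(parent) && parent[[cur]] %in% names(parent)) {
      if (cur %in% seen) stop("marker tree contains a cycle at ", cur)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  structure(list(parent = parent, branches = br$branch, markers = markers),
            class = "markerTree")
}

#' Count ancestral and derived reads per tree branch
#'
#' Reads covering each branch-defining marker are screened under the same
#' quality gates as genotype calling and tallied as supporting the
#' derived or the ancestral state. In `transversionsOnly` mode, C/T and
#' G/A markers -- the sites confusable with post-mortem deamination --
#' are ignored entirely.
#'
#' @param pileup A pileup `data.frame` for one individual.
#' @param tree A `markerTree`.
#' @param minBaseQuality,minMapQuality Phred thresholds (default 30).
#' @param endTrim Terminal bases ignored (default 5).
#' @param transversionsOnly Ignore C/T and G/A markers (default FALSE).
#' @return A `data.frame` per branch: `branch`, `derived`, `ancestral`,
#'   `markersCovered`.
#' @export
scoreBranches <- function(pileup, tree, minBaseQuality = 30L,
                          minMapQuality = 30L, endTrim = 5L,
                          transversionsOnly = FALSE) {
  mk <- tree$markers
  if (transversionsOnly) {
    pair <- paste0(pmin(mk$ancestral, mk$derived),
                   pmax(mk$ancestral, mk$derived))
    mk <- mk[!pair %in% c("CT", "AG"), , drop = FALSE]
  }
  hit <- match(paste(pileup$chrom, pileup$position),
               paste(mk$chrom, mk$site))
  ok <- !is.na(hit) &
        pileup$base_quality >= minBaseQuality &
        pileup$mapping_quality >= minMapQuality &
        pileup$read_position > endTrim &
        pileup$read_position <= pileup$read_length - endTrim
  p <- pileup[ok, , drop = FALSE]
  hit <- hit[ok]
  der <- p$base == mk$derived[hit]
  anc <- p$base == mk$ancestral[hit]
  out <- data.frame(branch = tree$branches, derived = 0L, ancestral = 0L,
                    markersCovered = 0L, stringsAsFactors = FALSE)
  if (nrow(p)) {
    db <- tapply(der, mk$branch[hit], sum)
    ab <- tapply(anc, mk$branch[hit], sum)
    cb <- tapply(mk$site[hit][der | anc], mk$branch[hit][der | anc],
                 function(v) length(unique(v)))
    out$derived <- as.integer(ifelse(is.na(db[out$branch]), 0, db[out$branch]))
    out$ancestral <- as.integer(ifelse(is.na(ab[out$branch]), 0, ab[out$branch]))
    out$markersCovered <- as.integer(ifelse(is.na(cb[out$branch]), 0,
                                            cb[out$branch]))
  }
  out
}

#' Assign a haplogroup from branch support
#'
#' The call is the deepest branch whose entire root-to-branch path has
#' more derived than ancestral read support among covered markers
#' (majority rule; a tie or an uncovered branch does not support the
#' path). Branches off the called path that nevertheless show derived
#' support are reported as conflicts. With no supported root branch the
#' call is `"unresolved"`.
#'
#' @param support Branch support from [scoreBranches()].
#' @param tree The `markerTree`.
#' @return A list with `call`, `path` (root-to-call branches) and
#'   `conflicts` (branches with derived support off the path).
#' @export
assignHaplogroup <- function(support, tree) {
  sup <- setNames(support$derived > support$ancestral &
                  support$markersCovered >= 1, support$branch)
  children <- split(names(tree$parent), unname(tree$parent))
  path <- character(0)
  frontier <- children[["root"]]
  repeat {
    nxt <- frontier[vapply(frontier, function(b) isTRUE(sup[[b]]), TRUE)]
    if (length(nxt) == 0) break
    if (length(nxt) > 1) break  # incompatible siblings: stop at parent
    path <- c(path, nxt)
    frontier <- children[[nxt]]
    if (is.null(frontier)) break
  }
  call <- if (length(path)) path[length(path)] else "unresolved"
  ## branches with derived support that are not on the called path
  offPath <- setdiff(support$branch[support$derived > 0], path)
  list(call = call, path = path, conflicts = offPath)
}
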