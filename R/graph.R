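#' Construct an AdmixtureGraph
#'
#' Edges are given as `(parent, child, drift)` triples; drift lengths are in
#' f2 units (Balding-Nichols variance fractions in the simulator). A node
#' with two incoming edges must be declared as an admixture node with a
#' mixing weight `alpha` on its first parent.
#'
#' @param edges A `data.frame` with columns `parent`, `child`, `drift`, or a
#'   character vector like `"root-A:0.01"` triples.
#' @param admixture Optional `data.frame` with columns `child`, `parentA`,
#'   `parentB`, `alpha`.
#' @return An [AdmixtureGraph-class].
#' @export
#' @examples
#' g <- AdmixtureGraph(data.frame(
#'   parent = c("root", "root", "X", "X"),
#'   child  = c("O", "X", "A", "B"),
#'   drift  = c(0, 0.02, 0.01, 0.01)))
#' graphLeaves(g)
AdmixtureGraph <- function(edges, admixture = NULL) {
  if (is.null(admixture))
    admixture <- data.frame(child = character(0), parentA = character(0),
                            parentB = character(0), alpha = numeric(0),
                            stringsAsFactors = FALSE)
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  edges$drift <- as.numeric(edges$drift)
  if (is.null(edges$fixed)) edges$fixed <- FALSE  # fixed-drift marker
  edges <- edges[, c("parent", "child", "drift", "fixed")]
  if (any(edges$drift < 0)) stop("drift lengths must be >= 0")
  if (nrow(admixture) && any(admixture$alpha < 0 | admixture$alpha > 1))
    stop("admixture weights must lie in [0, 1]")
  g <- new("AdmixtureGraph", edges = edges, admixture = admixture)
  validObject(g)
  g
}

#' @rdname adnapipe-generics
#' @export
setMethod("graphEdges", "AdmixtureGraph", function(x) x@edges)

#' @rdname adnapipe-generics
#' @export
setMethod("graphNodes", "AdmixtureGraph",
          function(x) .topoOrder(x@edges))

#' @rdname adnapipe-generics
#' @export
setMethod("graphRoot", "AdmixtureGraph",
          function(x) setdiff(x@edges$parent, x@edges$child))

#' @rdname adnapipe-generics
#' @export
setMethod("graphLeaves", "AdmixtureGraph",
          function(x) sort(setdiff(x@edges$child, x@edges$parent)))

#' @rdname adnapipe-generics
#' @export
setMethod("admixtureNodes", "AdmixtureGraph", function(x) x@admixture)

#' @export
setMethod("show", "AdmixtureGraph", function(object) {
  cat(sprintf("AdmixtureGraph: %d nodes, %d edges, %d admixture node(s); root %s; leaves: %s\n",
              length(graphNodes(object)), nrow(object@edges),
              nrow(object@admixture), graphRoot(object),
              paste(graphLeaves(object), collapse = ", ")))
})

#' Read / write admixture graphs as edge-list text
#'
#' The format has one line per edge, `parent child drift`, plus
#' `admix child parentA parentB alpha` lines for admixture nodes. Lines
#' starting with `#` are comments.
#'
#' @param path File path.
#' @return For the reader, an [AdmixtureGraph-class].
#' @export
readGraph <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  tok <- strsplit(ln, "[[:space:]]+")
  isAdm <- vapply(tok, function(t) t[1] == "admix", TRUE)
  e <- do.call(rbind, lapply(tok[!isAdm], function(t)
    data.frame(parent = t[1], child = t[2], drift = as.numeric(t[3]))))
  a <- NULL
  if (any(isAdm))
    a <- do.call(rbind, lapply(tok[isAdm], function(t)
      data.frame(child = t[2], parentA = t[3], parentB = t[4],
                 alpha = as.numeric(t[5]))))
  AdmixtureGraph(e, a)
}

#' @param graph An [AdmixtureGraph-class].
#' @rdname readGraph
#' @export
writeGraph <- function(graph, path) {
  e <- graph@edges
  out <- sprintf("%s %s %.10g", e$parent, e$child, e$drift)
  a <- graph@admixture
  if (nrow(a))
    out <- c(out, sprintf("admix %s %s %s %.10g", a$child, a$parentA,
                          a$parentB, a$alpha))
  writeLines(out, path)
  invisible(path)
}

#' Export an admixture graph in DOT format
#'
#' @param graph An [AdmixtureGraph-class].
#' @param path Output file.
#' @export
writeGraphDot <- function(graph, path) {
  e <- graph@edges
  adm <- graph@admixture$child
  lines <- c("digraph G {",
             sprintf("  \"%s\" [shape=%s];", graphNodes(graph),
                     ifelse(graphNodes(graph) %in% adm, "diamond", "ellipse")),
             sprintf("  \"%s\" -> \"%s\" [label=\"%.4g\"];",
                     e$parent, e$child, e$drift),
             "}")
  writeLines(lines, path)
  invisible(path)
}
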