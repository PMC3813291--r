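#' Anonymous (attribute-free) graphs and canonical hashing
#'
#' A graph framework discards atom types, charges, hybridizations and bond
#' orders, keeping only the vertex/edge topology.  `anonymize()` strips a
#' molecular graph down to this skeleton and attaches a canonical hash that
#' is invariant under any relabeling of the vertices, so that two frameworks
#' hash equal exactly when they are isomorphic.
#'
#' @param mol a `molecular_graph` (or an `anonymous_graph`, returned as is).
#' @return An `anonymous_graph`: list with `n` (vertex count), `edges`
#'   (two-column matrix of unordered vertex pairs) and `hash`.
#' @examples
#' anonymize(parse_smiles("c1ccccc1"))$hash ==
#'   anonymize(parse_smiles("C1CCCCC1"))$hash  # same 6-cycle topology
#' @export
anonymize <- function(mol) {
  if (inherits(mol, "anonymous_graph")) return(mol)
  stopifnot(inherits(mol, "molecular_graph"))
  edges <- as.matrix(mol$bonds[, c("i", "j"), drop = FALSE])
  dimnames(edges) <- NULL
  g <- anonymous_graph(nrow(mol$atoms), edges)
  g
}

#' @param n vertex count.
#' @param edges two-column matrix of 1-based vertex pairs.
#' @rdname anonymize
#' @export
anonymous_graph <- function(n, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) && (any(edges < 1L) || any(edges > n)))
    stop("edge endpoint outside 1..", n)
  g <- structure(list(n = as.integer(n), edges = edges, hash = NA_character_),
                 class = "anonymous_graph")
  g$hash <- canonical_hash(g)
  g
}

#' @export
print.anonymous_graph <- function(x, ...) {
  cat(sprintf("<anonymous_graph: %d nodes, %d edges, hash %s>\n",
              x$n, nrow(x$edges), x$hash))
  invisible(x)
}

#' Canonical hash of an anonymous graph
#'
#' Deterministic, relabeling-invariant string identifying the isomorphism
#' class of the graph: vertices are brought into canonical order (BLISS
#' canonical labeling, via igraph) and the hash is the sorted edge list of
#' the relabeled graph.
#'
#' @param g an `anonymous_graph`, or anything accepted by [anonymize()].
#' @return opaque character scalar.
#' @export
canonical_hash <- function(g) {
  if (inherits(g, "molecular_graph")) g <- anonymize(g)
  n <- g$n
  if (n == 0L) return("0|")
  if (nrow(g$edges) == 0L) return(paste0(n, "|"))
  ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  lab <- igraph::canonical_permutation(ig)$labeling
  e <- cbind(lab[g$edges[, 1]], lab[g$edges[, 2]])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  paste0(n, "|", paste(e[, 1], e[, 2], sep = "-", collapse = ","))
}

#' Write framework hashes as TSV
#'
#' @param mols list of `molecular_graph` objects.
#' @param path output file; columns `id`, `hash`.
#' @export
write_framework_hashes <- function(mols, path) {
  df <- data.frame(id = vapply(mols, function(m) m$id, ""),
                   hash = vapply(mols, function(m) anonymize(m)$hash, ""),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
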