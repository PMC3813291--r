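#' Molecular graph objects
#'
#' A molecular graph stores heavy atoms as vertices and bonds as edges.
#' Hydrogens are implicit: each atom carries an implicit hydrogen count.
#' Atoms additionally carry a formal charge, an aromaticity flag (set when a
#' ring was written in aromatic form) and a `pi_marker` count.  The pi marker
#' is the "dot pair" annotation: when scaffold extraction removes a side-chain
#' atom that was multiply bonded to a retained atom, the retained atom keeps a
#' marker for the orphaned pi electrons so its hybridization stays readable.
#' Freshly parsed molecules always have `pi_marker == 0`.
#'
#' @param atoms data.frame with columns `element` (character), `charge`
#'   (integer), `hcount` (non-negative integer), `pi_marker` (non-negative
#'   integer) and `aromatic` (logical).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices),
#'   `order` (1, 2 or 3) and `aromatic` (logical).
#' @param id free-text identifier.
#'
#' @return An object of class `molecular_graph`.
#' @export
molecular_graph <- function(atoms, bonds, id = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  for (col in c("charge", "hcount", "pi_marker")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- 0L
    atoms[[col]] <- as.integer(atoms[[col]])
  }
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (nrow(bonds) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer(),
                        aromatic = logical())
  } else {
    bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                        order = as.integer(bonds$order),
                        aromatic = if (is.null(bonds$aromatic)) FALSE else
                          as.logical(bonds$aromatic))
  }
  mol <- structure(list(atoms = atoms, bonds = bonds, id = as.character(id)),
                   class = "molecular_graph")
  validate_molecular_graph(mol)
  mol
}

validate_molecular_graph <- function(mol) {
  n <- nrow(mol$atoms)
  b <- mol$bonds
  if (nrow(b)) {
    if (any(b$i < 1L | b$i > n | b$j < 1L | b$j > n))
      stop("bond refers to an atom index outside 1..", n)
    if (any(b$i == b$j)) stop("self-bonds are not allowed")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) stop("duplicate bond between an atom pair")
    if (!all(b$order %in% 1:3)) stop("bond orders must be 1, 2 or 3")
  }
  if (any(mol$atoms$hcount < 0L)) stop("negative implicit hydrogen count")
  if (any(mol$atoms$pi_marker < 0L)) stop("negative pi_marker")
  invisible(mol)
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph%s: %d heavy atoms, %d bonds, formula %s>\n",
              if (nzchar(x$id)) paste0(" ", x$id) else "",
              nrow(x$atoms), nrow(x$bonds), molecular_formula(x)))
  invisible(x)
}

#' Number of heavy atoms
#' @param mol a `molecular_graph`.
#' @return Integer count of non-hydrogen atoms.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

# Hill-order molecular formula including implicit hydrogens.
#' @rdname molecular_graph
#' @export
molecular_formula <- function(atoms) {
  mol <- atoms
  counts <- table(mol$atoms$element)
  h <- sum(mol$atoms$hcount)
  els <- names(counts)
  ord <- c(intersect("C", els), if (h > 0) "H", sort(setdiff(els, c("C", "H"))))
  parts <- vapply(ord, function(e) {
    k <- if (e == "H") h + sum(counts[names(counts) == "H"]) else counts[[e]]
    paste0(e, if (k > 1) k else "")
  }, "")
  paste(parts, collapse = "")
}

# igraph view of the heavy-atom skeleton (undirected, vertex order preserved)
mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms))))
}

# neighbour list: integer vector of bonded atoms per atom
mol_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  adj
}

# sum of bond orders per atom (aromatic bonds carry their kekulized order)
mol_bond_order_sum <- function(mol) {
  n <- nrow(mol$atoms)
  s <- integer(n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    s[b$i[k]] <- s[b$i[k]] + b$order[k]
    s[b$j[k]] <- s[b$j[k]] + b$order[k]
  }
  s
}

# induced subgraph on a set of atom indices; bonds renumbered
mol_subgraph <- function(mol, keep, id = mol$id) {
  keep <- sort(unique(as.integer(keep)))
  map <- integer(nrow(mol$atoms))
  map[keep] <- seq_along(keep)
  b <- mol$bonds
  sel <- b$i %in% keep & b$j %in% keep
  nb <- b[sel, , drop = FALSE]
  nb$i <- map[nb$i]
  nb$j <- map[nb$j]
  out <- structure(list(atoms = mol$atoms[keep, , drop = FALSE],
                        bonds = nb, id = id),
                   class = "molecular_graph")
  rownames(out$atoms) <- NULL
  rownames(out$bonds) <- NULL
  out
}

# standard valences used to fill implicit hydrogens (Daylight convention)
.standard_valences <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L)

# check bond-order sum + implicit H against standard valence for the
# uncharged organic elements; returns indices of offending atoms.  Atoms
# carrying a dot pair are exempt: the marker stands for pi electrons whose
# bonding partner was removed, so their valence is reduced by construction.
mol_valence_violations <- function(mol) {
  s <- mol_bond_order_sum(mol)
  bad <- integer()
  for (a in seq_len(nrow(mol$atoms))) {
    el <- mol$atoms$element[a]
    if (mol$atoms$charge[a] != 0L || mol$atoms$pi_marker[a] > 0L ||
        !el %in% c("C", "N", "O", "S")) next
    tot <- s[a] + mol$atoms$hcount[a]
    if (!tot %in% .standard_valences[[el]]) bad <- c(bad, a)
  }
  bad
}
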