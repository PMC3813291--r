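#' Ring system perception
#'
#' A ring system is a maximal set of cycles pairwise connected through shared
#' atoms: fused bicycles and spiro junctions both form a single system, while
#' rings joined only by a bond (biphenyl) remain separate systems.  Ring
#' bonds are the non-bridge edges of the molecular graph; ring systems are
#' the connected components of the subgraph they induce.
#'
#' @param mol a `molecular_graph`.
#' @return list of ring systems, each a list with `atoms` (sorted atom
#'   indices) and `n_rings` (cyclomatic count of the system).  Acyclic input
#'   gives an empty list.
#' @export
perceive_ring_systems <- function(mol) {
  nb <- nrow(mol$bonds)
  if (!nb) return(list())
  ring_bond <- .ring_bond_flags(mol)
  if (!any(ring_bond)) return(list())
  rb <- mol$bonds[ring_bond, , drop = FALSE]
  g <- igraph::graph_from_data_frame(rb[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms))))
  comp <- igraph::components(g)
  out <- list()
  for (cid in seq_len(comp$no)) {
    verts <- which(comp$membership == cid)
    if (length(verts) < 3L) next  # isolated atoms carry no ring bonds
    edges_in <- sum(rb$i %in% verts & rb$j %in% verts)
    out[[length(out) + 1L]] <- list(atoms = sort(as.integer(verts)),
                                    n_rings = edges_in - length(verts) + 1L)
  }
  out
}

#' Atom role classification
#'
#' Partitions every atom into exactly one of three roles:
#' * `RING` — atoms lying in at least one cycle;
#' * `LINKER` — non-ring atoms on a path connecting two ring systems whose
#'   interior avoids ring atoms, plus any non-ring atom attached to such a
#'   path atom by a double or triple bond (functional groups such as linker
#'   carbonyls are retained, not eliminated);
#' * `SIDE_CHAIN` — all remaining non-ring atoms.
#'
#' @param mol a `molecular_graph`.
#' @param systems ring systems from [perceive_ring_systems()]; computed if
#'   missing.
#' @return character vector of roles, one per atom.
#' @export
classify_atoms <- function(mol, systems = perceive_ring_systems(mol)) {
  n <- nrow(mol$atoms)
  roles <- rep("SIDE_CHAIN", n)
  ring_atoms <- sort(unique(unlist(lapply(systems, `[[`, "atoms"))))
  roles[ring_atoms] <- "RING"
  if (length(systems) < 2L || n == length(ring_atoms)) return(roles)

  system_of <- integer(n)
  for (s in seq_along(systems)) system_of[systems[[s]]$atoms] <- s

  adj <- mol_adjacency(mol)
  nonring <- setdiff(seq_len(n), ring_atoms)
  # connected components of the non-ring atoms; each is acyclic (a tree),
  # since any cycle would have made its atoms ring atoms
  comp_id <- integer(n)
  cid <- 0L
  for (start in nonring) {
    if (comp_id[start]) next
    cid <- cid + 1L
    queue <- start
    comp_id[start] <- cid
    while (length(queue)) {
      a <- queue[1L]; queue <- queue[-1L]
      for (b in adj[[a]]) {
        if (!comp_id[b] && roles[b] != "RING") {
          comp_id[b] <- cid
          queue <- c(queue, b)
        }
      }
    }
  }

  linker <- rep(FALSE, n)
  for (c in seq_len(cid)) {
    members <- which(comp_id == c)
    # ring systems this component touches, per member atom
    touched <- lapply(members, function(a)
      unique(system_of[adj[[a]][roles[adj[[a]]] == "RING"]]))
    all_sys <- unique(unlist(touched))
    if (length(all_sys) < 2L) next
    # the linker core is the minimal subtree spanning the attachment atoms:
    # iteratively prune non-attachment leaves of the component tree
    attach <- members[vapply(touched, length, 0L) > 0L]
    keep <- members
    repeat {
      degs <- vapply(keep, function(a) sum(adj[[a]] %in% keep), 0L)
      drop <- keep[degs <= 1L & !(keep %in% attach)]
      if (!length(drop)) break
      keep <- setdiff(keep, drop)
    }
    linker[keep] <- TRUE
  }

  # retained functional groups: non-ring atoms multiply bonded to a linker
  # atom become linkers themselves (to a fixpoint, for chained cases)
  b <- mol$bonds
  repeat {
    grew <- FALSE
    for (k in seq_len(nrow(b))) {
      if (b$order[k] < 2L) next
      i <- b$i[k]; j <- b$j[k]
      if (linker[i] && !linker[j] && roles[j] != "RING") { linker[j] <- TRUE; grew <- TRUE }
      if (linker[j] && !linker[i] && roles[i] != "RING") { linker[i] <- TRUE; grew <- TRUE }
    }
    if (!grew) break
  }
  roles[linker] <- "LINKER"
  roles
}

#' Scaffold (simplified structure) extraction
#'
#' The scaffold is the induced subgraph on the RING and LINKER atoms.  When a
#' removed side-chain atom was attached to a retained atom by a double
#' (triple) bond, the retained atom's `pi_marker` is incremented by 1 (2) —
#' the "dot pair" annotation that preserves the sp2 character of the atom
#' after its substituent is gone.  Side chains cut at a single bond leave an
#' additional implicit hydrogen instead.
#'
#' @param mol a `molecular_graph`.
#' @param roles atom roles from [classify_atoms()]; computed if missing.
#' @return a `molecular_graph` scaffold.
#' @export
extract_scaffold <- function(mol, roles = classify_atoms(mol)) {
  keep <- which(roles != "SIDE_CHAIN")
  if (!length(keep))
    stop("empty scaffold: molecule has no ring system (all atoms side chain)")
  kept <- rep(FALSE, nrow(mol$atoms))
  kept[keep] <- TRUE
  pi_add <- integer(nrow(mol$atoms))
  h_add <- integer(nrow(mol$atoms))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    if (kept[i] == kept[j]) next
    a <- if (kept[i]) i else j           # retained endpoint of the cut bond
    if (b$order[k] == 1L) h_add[a] <- h_add[a] + 1L
    else pi_add[a] <- pi_add[a] + (b$order[k] - 1L)
  }
  scaf <- mol_subgraph(mol, keep, id = mol$id)
  scaf$atoms$pi_marker <- scaf$atoms$pi_marker + pi_add[keep]
  scaf$atoms$hcount <- scaf$atoms$hcount + h_add[keep]
  scaf
}

#' Framework extraction
#'
#' The framework of a scaffold is its anonymous graph: atom types, charges,
#' hybridizations and bond orders discarded, topology and canonical hash
#' retained.
#'
#' @param scaffold a non-empty `molecular_graph` scaffold.
#' @return an `anonymous_graph`.
#' @export
extract_framework <- function(scaffold) {
  if (!inherits(scaffold, "molecular_graph") || nrow(scaffold$atoms) == 0L)
    stop("framework extraction needs a non-empty scaffold")
  anonymize(scaffold)
}

#' Full hierarchical dissection of one molecule
#'
#' Runs ring perception, atom role classification, scaffold and framework
#' extraction, and collects the side-chain and linker fragments (connected
#' components of the atoms of each role).
#'
#' @param mol a `molecular_graph`.
#' @return object of class `dissection`: list with `mol`, `roles`,
#'   `ring_systems`, `scaffold`, `framework`, `side_chain_fragments`,
#'   `linker_fragments`.
#' @export
dissect_molecule <- function(mol) {
  systems <- perceive_ring_systems(mol)
  if (!length(systems))
    stop(sprintf("molecule %s is acyclic: no scaffold can be extracted",
                 mol$id))
  roles <- classify_atoms(mol, systems)
  scaffold <- extract_scaffold(mol, roles)
  structure(list(
    mol = mol,
    roles = roles,
    ring_systems = systems,
    scaffold = scaffold,
    framework = extract_framework(scaffold),
    side_chain_fragments = .role_fragments(mol, roles, "SIDE_CHAIN"),
    linker_fragments = .role_fragments(mol, roles, "LINKER")),
    class = "dissection")
}

.role_fragments <- function(mol, roles, role) {
  sel <- which(roles == role)
  if (!length(sel)) return(list())
  sub <- mol_subgraph(mol, sel, id = mol$id)
  g <- mol_igraph(sub)
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(cid) {
    frag <- mol_subgraph(sub, which(comp$membership == cid),
                         id = sprintf("%s/%s%d", mol$id, tolower(role), cid))
    frag
  })
}

#' @export
print.dissection <- function(x, ...) {
  cat(sprintf("<dissection of %s>\n", x$mol$id))
  cat(sprintf("  atoms: %d (%d ring, %d linker, %d side chain)\n",
              length(x$roles), sum(x$roles == "RING"),
              sum(x$roles == "LINKER"), sum(x$roles == "SIDE_CHAIN")))
  cat(sprintf("  ring systems: %d; scaffold: %d atoms; framework hash: %s\n",
              length(x$ring_systems), nrow(x$scaffold$atoms),
              x$framework$hash))
  invisible(x)
}

#' Group molecules by graph framework
#'
#' Dissects every molecule and partitions the identifiers by the canonical
#' hash of their frameworks.  Groups are ordered by descending member count,
#' then lexicographically by hash; members keep input order.
#'
#' @param mols list of `molecular_graph` objects (each with at least one
#'   ring).
#' @return data.frame with columns `hash`, `count`, `members`
#'   (comma-separated ids), plus attribute `groups` (named list of id
#'   vectors).
#' @export
group_by_framework <- function(mols) {
  ids <- vapply(mols, function(m) m$id, "")
  hashes <- vapply(mols, function(m) dissect_molecule(m)$framework$hash, "")
  groups <- split(ids, hashes)
  ord <- order(-vapply(groups, length, 0L), names(groups))
  groups <- groups[ord]
  df <- data.frame(hash = names(groups),
                   count = vapply(groups, length, 0L),
                   members = vapply(groups, paste, "", collapse = ","),
                   stringsAsFactors = FALSE, row.names = NULL)
  attr(df, "groups") <- groups
  df
}
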