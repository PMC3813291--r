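#' Serialize a molecular graph to SMILES
#'
#' Depth-first serialization in Kekulized (uppercase) form: double and
#' triple bonds are written explicitly, ring closures use numeric labels,
#' and atoms are bracketed whenever charge or hydrogen count cannot be
#' inferred from standard valence.  Dot-pair markers have no SMILES
#' representation and are dropped; round-tripping a scaffold therefore
#' preserves topology, elements, charges and hydrogen counts, but not the
#' `pi_marker` annotation.
#'
#' @param mol a `molecular_graph`.
#' @return a SMILES string (disconnected components joined by `.`).
#' @export
smiles_string <- function(mol) {
  n <- nrow(mol$atoms)
  if (!n) stop("cannot serialize an empty molecule")
  adj <- vector("list", n)         # per atom: list of c(neighbour, bond row)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], list(c(b$j[k], k)))
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], list(c(b$i[k], k)))
  }
  bond_sym <- c("", "=", "#")
  bsum <- mol_bond_order_sum(mol)

  atom_token <- function(a) {
    el <- mol$atoms$element[a]
    ch <- mol$atoms$charge[a]
    h <- mol$atoms$hcount[a]
    if (el %in% .organic_aliphatic && ch == 0L &&
        mol$atoms$pi_marker[a] == 0L) {
      targets <- .standard_valences[[el]]
      fit <- targets[targets >= bsum[a]]
      if (length(fit) && (min(fit) - bsum[a]) == h) return(el)
    }
    paste0("[", el,
           if (h == 1L) "H" else if (h > 1L) paste0("H", h) else "",
           if (ch > 0L) paste0("+", if (ch > 1L) ch else "") else "",
           if (ch < 0L) paste0("-", if (ch < -1L) -ch else "") else "", "]")
  }

  # pass 1: DFS spanning forest; classify tree and back edges, assign ring
  # closure labels to both endpoints of every back edge
  visited <- logical(n)
  edge_state <- integer(nrow(b))   # 0 unseen, 1 tree, 2 back
  tree_children <- vector("list", n)
  closure_tok <- vector("list", n)
  ring_label <- 0L
  roots <- integer()
  walk <- function(a) {
    visited[a] <<- TRUE
    for (nb in adj[[a]]) {
      v <- nb[1]; k <- nb[2]
      if (edge_state[k]) next
      if (visited[v]) {
        edge_state[k] <<- 2L
        ring_label <<- ring_label + 1L
        lbl <- if (ring_label > 9L) paste0("%",
          formatC(ring_label, width = 2, flag = "0")) else
          as.character(ring_label)
        tok <- paste0(bond_sym[b$order[k]], lbl)
        closure_tok[[a]] <<- c(closure_tok[[a]], tok)
        closure_tok[[v]] <<- c(closure_tok[[v]], tok)
      } else {
        edge_state[k] <<- 1L
        tree_children[[a]] <<- c(tree_children[[a]], list(c(v, k)))
        walk(v)
      }
    }
  }
  for (start in seq_len(n)) {
    if (!visited[start]) { roots <- c(roots, start); walk(start) }
  }

  # pass 2: emit along the spanning forest
  emit <- function(a) {
    out <- paste0(atom_token(a), paste(closure_tok[[a]], collapse = ""))
    kids <- tree_children[[a]]
    if (length(kids)) {
      branches <- vapply(kids, function(nb)
        paste0(bond_sym[b$order[nb[2]]], emit(nb[1])), "")
      out <- paste0(out,
                    if (length(branches) > 1L)
                      paste0("(", branches[-length(branches)], ")",
                             collapse = "") else "",
                    branches[length(branches)])
    }
    out
  }
  paste(vapply(roots, emit, ""), collapse = ".")
}

#' Write molecules to a SMILES file
#' @param mols list of `molecular_graph` objects.
#' @param path output path; lines are `SMILES<TAB>id`.
#' @export
write_smiles <- function(mols, path) {
  writeLines(vapply(mols, function(m)
    paste(smiles_string(m), m$id, sep = "\t"), ""), path)
  invisible(path)
}
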