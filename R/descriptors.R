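# IUPAC 2021 conventional/abridged average atomic masses, 3 decimals
.atomic_masses <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.060,
  Cl = 35.450, K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.380,
  Se = 78.971, Br = 79.904, I = 126.904)

#' Heavy atom count
#'
#' Number of non-hydrogen atoms (HAC), the denominator of the ligand
#' efficiency index.
#'
#' @param mol a `molecular_graph`.
#' @return integer.
#' @export
heavy_atom_count <- function(mol) nrow(mol$atoms)

#' Molecular weight
#'
#' Sum of average atomic masses over heavy atoms and implicit hydrogens.
#'
#' @param mol a `molecular_graph`.
#' @return weight in daltons.
#' @export
molecular_weight <- function(mol) {
  els <- mol$atoms$element
  unknown <- setdiff(unique(els), names(.atomic_masses))
  if (length(unknown))
    stop("element(s) missing from the atomic mass table: ",
         paste(unknown, collapse = ", "))
  sum(.atomic_masses[els]) + sum(mol$atoms$hcount) * .atomic_masses[["H"]]
}

#' Hydrogen-bond donor count
#'
#' Number of hydrogens borne by nitrogen or oxygen atoms (an NH2 group
#' contributes two donors).
#'
#' @param mol a `molecular_graph`.
#' @return integer.
#' @export
hbd_count <- function(mol) {
  sel <- mol$atoms$element %in% c("N", "O")
  sum(mol$atoms$hcount[sel])
}

#' Hydrogen-bond acceptor count
#'
#' Number of nitrogen and oxygen atoms that are plausible acceptors:
#' positively charged atoms are excluded, as is the pyrrole-type nitrogen
#' (an N-H nitrogen inside an aromatic five-membered ring), whose lone pair
#' is part of the aromatic sextet.
#'
#' @param mol a `molecular_graph`.
#' @return integer.
#' @export
hba_count <- function(mol) {
  n <- 0L
  in5 <- .atoms_in_aromatic_5ring(mol)
  for (a in seq_len(nrow(mol$atoms))) {
    el <- mol$atoms$element[a]
    if (!el %in% c("N", "O")) next
    if (mol$atoms$charge[a] > 0L) next
    if (el == "N" && mol$atoms$aromatic[a] && mol$atoms$hcount[a] > 0L && in5[a])
      next
    n <- n + 1L
  }
  n
}

# flag atoms that sit in at least one aromatic ring of size 5
.atoms_in_aromatic_5ring <- function(mol) {
  n <- nrow(mol$atoms)
  res <- logical(n)
  arom <- mol$bonds[mol$bonds$aromatic, , drop = FALSE]
  if (!nrow(arom)) return(res)
  g <- igraph::graph_from_data_frame(arom[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  # 5-cycles in the aromatic-bond subgraph
  for (a in which(igraph::degree(g) >= 2)) {
    if (res[a]) next
    # any closed walk of length 5 through a that is a simple cycle
    paths <- igraph::all_simple_paths(g, from = a, cutoff = 4)
    for (p in paths) {
      v <- as.integer(igraph::as_ids(p))
      if (length(v) == 5L &&
          igraph::are_adjacent(g, as.character(v[5L]), as.character(a)))
        res[v] <- TRUE
    }
  }
  res
}

#' Rotatable bond count
#'
#' Non-ring single bonds between two non-terminal heavy atoms, excluding
#' amide C-N bonds (a C-N single bond whose carbon carries a double-bonded
#' oxygen).
#'
#' @param mol a `molecular_graph`.
#' @return integer.
#' @export
rotatable_bond_count <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(0L)
  deg <- integer(nrow(mol$atoms))
  for (k in seq_len(nrow(b))) {
    deg[b$i[k]] <- deg[b$i[k]] + 1L
    deg[b$j[k]] <- deg[b$j[k]] + 1L
  }
  ring_bond <- .ring_bond_flags(mol)
  # carbons bearing a double-bonded oxygen (amide/acid carbonyl carbons)
  carbonyl_c <- rep(FALSE, nrow(mol$atoms))
  for (k in seq_len(nrow(b))) {
    if (b$order[k] == 2L) {
      ei <- mol$atoms$element[b$i[k]]; ej <- mol$atoms$element[b$j[k]]
      if (ei == "C" && ej == "O") carbonyl_c[b$i[k]] <- TRUE
      if (ej == "C" && ei == "O") carbonyl_c[b$j[k]] <- TRUE
    }
  }
  n <- 0L
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 1L || ring_bond[k]) next
    if (deg[b$i[k]] < 2L || deg[b$j[k]] < 2L) next
    ei <- mol$atoms$element[b$i[k]]; ej <- mol$atoms$element[b$j[k]]
    amide <- (ei == "C" && ej == "N" && carbonyl_c[b$i[k]]) ||
             (ej == "C" && ei == "N" && carbonyl_c[b$j[k]])
    if (amide) next
    n <- n + 1L
  }
  n
}

# logical flag per bond: TRUE if the bond lies in a cycle (is not a bridge)
.ring_bond_flags <- function(mol) {
  nb <- nrow(mol$bonds)
  if (!nb) return(logical(0))
  g <- mol_igraph(mol)
  flags <- rep(TRUE, nb)
  flags[as.integer(igraph::bridges(g))] <- FALSE
  flags
}

#' Full descriptor set
#'
#' @param mol a `molecular_graph`.
#' @return one-row data.frame with columns `id`, `HAC`, `MW`, `HBD`, `HBA`,
#'   `RotB`.
#' @export
descriptor_set <- function(mol) {
  data.frame(id = mol$id,
             HAC = heavy_atom_count(mol),
             MW = round(molecular_weight(mol), 2),
             HBD = hbd_count(mol),
             HBA = hba_count(mol),
             RotB = rotatable_bond_count(mol),
             stringsAsFactors = FALSE)
}

#' Descriptor table for a list of molecules
#' @param mols list of `molecular_graph` objects.
#' @return data.frame, one row per molecule.
#' @export
descriptor_table <- function(mols) {
  do.call(rbind, lapply(mols, descriptor_set))
}

#' Filter molecules by rotatable bond count
#'
#' Selection gate used before docking-style scoring: structures with more
#' than `threshold` rotatable bonds are set aside.
#'
#' @param mols list of `molecular_graph` objects.
#' @param threshold maximum rotatable bonds retained (default 10;
#'   "10 or less" passes).
#' @return list with elements `kept` and `discarded`.
#' @export
filter_by_rotb <- function(mols, threshold = 10L) {
  rotb <- vapply(mols, rotatable_bond_count, 0L)
  list(kept = mols[rotb <= threshold], discarded = mols[rotb > threshold])
}
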