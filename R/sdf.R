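#' Read molecules from an SDF/MOL file (V2000)
#'
#' Record parsing is delegated to \pkg{ChemmineR}; atom and bond blocks are
#' converted into `molecular_graph` objects.  Explicit hydrogen atoms are
#' folded into the implicit hydrogen count of their heavy neighbour, and
#' remaining implicit hydrogens are filled by standard valence.  Formal
#' charges are taken from the atom-block charge field (old-style codes);
#' `M  CHG` property lines are not interpreted by the reader.
#'
#' @param path file path.
#' @return list of `molecular_graph` objects; an empty file yields an empty
#'   list with a warning.
#' @export
read_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("read_sdf requires the ChemmineR package")
  if (!file.size(path)) {
    warning("empty SDF file: ", path)
    return(list())
  }
  sdfset <- tryCatch(ChemmineR::read.SDFset(path),
                     error = function(e)
                       stop("SDF format error: ", conditionMessage(e),
                            call. = FALSE))
  out <- vector("list", length(sdfset))
  for (k in seq_along(sdfset)) {
    out[[k]] <- tryCatch(.sdf_record_to_graph(sdfset[[k]], k),
                         error = function(e)
                           stop(sprintf("SDF format error in record %d: %s",
                                        k, conditionMessage(e)), call. = FALSE))
  }
  out
}

# old-style MOL atom-block charge codes
.mol_charge_codes <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L,
                       `7` = -3L)

.sdf_record_to_graph <- function(sdf, index) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  na <- length(elements)
  charge_col <- if (ncol(ab) >= 6) ab[, 6] else rep(0, na)
  charges <- vapply(as.character(charge_col), function(code) {
    v <- .mol_charge_codes[code]
    if (is.na(v)) 0L else v
  }, 0L)
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]), aromatic = FALSE)
  if (any(bonds$order == 4L)) stop("aromatic bond type 4 not supported; ",
                                   "supply a Kekulized record")
  # fold explicit hydrogens into the heavy neighbour's implicit count
  is_h <- elements == "H"
  hcount <- integer(na)
  if (any(is_h)) {
    keep_bond <- rep(TRUE, nrow(bonds))
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$i[k]; j <- bonds$j[k]
      if (is_h[i] && !is_h[j]) { hcount[j] <- hcount[j] + 1L; keep_bond[k] <- FALSE }
      else if (is_h[j] && !is_h[i]) { hcount[i] <- hcount[i] + 1L; keep_bond[k] <- FALSE }
      else if (is_h[i] && is_h[j]) stop("H-H bond in record")
    }
    bonds <- bonds[keep_bond, , drop = FALSE]
  }
  atoms <- data.frame(element = elements, charge = charges, hcount = hcount,
                      pi_marker = 0L, aromatic = FALSE,
                      stringsAsFactors = FALSE)
  keep <- which(!is_h)
  mol <- molecular_graph(atoms[keep, , drop = FALSE],
                         .renumber_bonds(bonds, keep, na),
                         id = paste0("sdf", index))
  # fill remaining implicit hydrogens by standard valence
  bsum <- mol_bond_order_sum(mol)
  for (a in seq_len(nrow(mol$atoms))) {
    el <- mol$atoms$element[a]
    targets <- .standard_valences[[el]]
    if (is.null(targets) || mol$atoms$charge[a] != 0L) next
    fit <- targets[targets >= bsum[a] + mol$atoms$hcount[a]]
    if (length(fit))
      mol$atoms$hcount[a] <- min(fit) - bsum[a]
  }
  mol
}

.renumber_bonds <- function(bonds, keep, n) {
  map <- integer(n)
  map[keep] <- seq_along(keep)
  bonds$i <- map[bonds$i]
  bonds$j <- map[bonds$j]
  bonds
}
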