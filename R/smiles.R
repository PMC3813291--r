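#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset (B, C, N, O, P, S, F, Cl, Br, I), aromatic
#' lowercase atoms, branches, ring closures (including `%nn`), bracket atoms
#' with charge and explicit hydrogen counts, and the bond symbols
#' `- = # : / \`.  Directional bonds and chirality marks are parsed and
#' discarded; all downstream computation ignores stereochemistry.  Aromatic
#' perception is limited to rings written in aromatic (lowercase) form; such
#' rings are Kekulized internally to alternating single/double bonds so that
#' every bond has a definite order, while the aromatic flag is retained on
#' atoms and ring bonds for descriptor logic.
#'
#' @param text a single SMILES string.
#' @param id identifier attached to the resulting graph.
#' @return A [molecular_graph()] with implicit hydrogens filled by standard
#'   valence.
#' @examples
#' parse_smiles("c1ccccc1", id = "benzene")
#' parse_smiles("C1CC1C(=O)O")
#' @export
parse_smiles <- function(text, id = "") {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("SMILES input must be a single non-empty string")
  st <- .smiles_tokenize_and_build(text)
  mol <- .smiles_finalize(st, text, id)
  mol
}

.smiles_error <- function(msg, pos, text) {
  stop(sprintf("SMILES parse error at position %d ('%s'): %s",
               pos, substr(text, pos, min(pos + 4L, nchar(text))), msg),
       call. = FALSE)
}

.organic_aliphatic <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.organic_aromatic <- c("b", "c", "n", "o", "p", "s")

.smiles_tokenize_and_build <- function(text) {
  chars <- strsplit(text, "")[[1]]
  nch <- length(chars)
  atoms <- list()     # each: list(element, charge, hcount(NA=implicit), aromatic)
  bonds <- list()     # each: list(i, j, sym)  sym: "", "-", "=", "#", ":"
  prev <- NA_integer_
  pending <- ""       # bond symbol awaiting next atom
  stack <- integer()
  ring <- list()      # closure label -> list(atom, sym, pos)

  add_atom <- function(element, charge, hcount, aromatic, pos) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, charge = charge,
                                         hcount = hcount, aromatic = aromatic)
    idx <- length(atoms)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1L]] <<- list(i = prev, j = idx, sym = pending)
    }
    pending <<- ""
    prev <<- idx
    invisible(idx)
  }

  close_ring <- function(label, pos) {
    if (is.na(prev))
      .smiles_error("ring closure before any atom", pos, text)
    if (!is.null(ring[[label]])) {
      op <- ring[[label]]
      sym <- if (nzchar(pending)) pending else op$sym
      if (nzchar(pending) && nzchar(op$sym) && pending != op$sym)
        .smiles_error("conflicting bond symbols on ring closure", pos, text)
      if (op$atom == prev)
        .smiles_error("ring closure to the same atom", pos, text)
      bonds[[length(bonds) + 1L]] <<- list(i = op$atom, j = prev, sym = sym)
      ring[[label]] <<- NULL
    } else {
      ring[[label]] <- list(atom = prev, sym = pending, pos = pos)
      ring <<- ring
    }
    pending <<- ""
  }

  i <- 1L
  while (i <= nch) {
    ch <- chars[i]
    two <- if (i < nch) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      add_atom(two, 0L, NA_integer_, FALSE, i); i <- i + 2L
    } else if (ch %in% .organic_aliphatic) {
      add_atom(ch, 0L, NA_integer_, FALSE, i); i <- i + 1L
    } else if (ch %in% .organic_aromatic) {
      add_atom(toupper(ch), 0L, NA_integer_, TRUE, i); i <- i + 1L
    } else if (ch == "[") {
      res <- .parse_bracket(chars, i, text)
      add_atom(res$element, res$charge, res$hcount, res$aromatic, i)
      i <- res$next_i
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- if (ch %in% c("/", "\\")) "-" else ch
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) .smiles_error("branch before any atom", i, text)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) .smiles_error("unmatched ')'", i, text)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch, i); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > nch || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
        .smiles_error("'%' must be followed by two digits", i, text)
      close_ring(paste0(chars[i + 1L], chars[i + 2L]), i)
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- ""; i <- i + 1L
    } else if (grepl("[A-Za-z]", ch)) {
      .smiles_error(sprintf("unsupported element or token '%s'", ch), i, text)
    } else {
      .smiles_error(sprintf("unexpected character '%s'", ch), i, text)
    }
  }
  if (length(stack)) .smiles_error("unclosed '('", nch, text)
  if (length(ring)) {
    op <- ring[[1]]
    .smiles_error(sprintf("unclosed ring bond '%s'", names(ring)[1]), op$pos, text)
  }
  if (!length(atoms)) .smiles_error("no atoms found", 1L, text)
  list(atoms = atoms, bonds = bonds)
}

# bracket atom: [isotope? symbol chiral? Hcount? charge? :class?]
.parse_bracket <- function(chars, start, text) {
  i <- start + 1L
  nch <- length(chars)
  take_digits <- function() {
    d <- ""
    while (i <= nch && grepl("[0-9]", chars[i])) { d <- paste0(d, chars[i]); i <<- i + 1L }
    d
  }
  take_digits()  # isotope, ignored
  if (i > nch) .smiles_error("unterminated bracket atom", start, text)
  aromatic <- FALSE
  if (grepl("[a-z]", chars[i]) && chars[i] %in% c(.organic_aromatic)) {
    element <- toupper(chars[i]); aromatic <- TRUE; i <- i + 1L
  } else if (grepl("[A-Z]", chars[i])) {
    element <- chars[i]; i <- i + 1L
    if (i <= nch && grepl("[a-z]", chars[i]) &&
        paste0(element, chars[i]) %in% names(.atomic_masses)) {
      element <- paste0(element, chars[i]); i <- i + 1L
    }
  } else .smiles_error("expected element symbol in bracket", i, text)
  if (!element %in% names(.atomic_masses))
    stop(sprintf("unsupported element '%s' at position %d", element, start),
         call. = FALSE)
  while (i <= nch && chars[i] == "@") i <- i + 1L  # chirality, ignored
  hcount <- 0L
  if (i <= nch && chars[i] == "H") {
    i <- i + 1L
    d <- take_digits()
    hcount <- if (nzchar(d)) as.integer(d) else 1L
  }
  charge <- 0L
  while (i <= nch && chars[i] %in% c("+", "-")) {
    sgn <- if (chars[i] == "+") 1L else -1L
    i <- i + 1L
    d <- take_digits()
    charge <- charge + sgn * (if (nzchar(d)) as.integer(d) else 1L)
  }
  if (i <= nch && chars[i] == ":") { i <- i + 1L; take_digits() }  # atom class
  if (i > nch || chars[i] != "]")
    .smiles_error("unterminated bracket atom", start, text)
  list(element = element, charge = charge, hcount = hcount,
       aromatic = aromatic, next_i = i + 1L)
}

.smiles_finalize <- function(st, text, id) {
  na <- length(st$atoms)
  atoms <- data.frame(
    element = vapply(st$atoms, `[[`, "", "element"),
    charge = vapply(st$atoms, `[[`, 0L, "charge"),
    hcount = vapply(st$atoms, `[[`, NA_integer_, "hcount"),
    pi_marker = 0L,
    aromatic = vapply(st$atoms, `[[`, FALSE, "aromatic"),
    stringsAsFactors = FALSE)
  nb <- length(st$bonds)
  bonds <- data.frame(
    i = vapply(st$bonds, `[[`, 0L, "i"),
    j = vapply(st$bonds, `[[`, 0L, "j"),
    sym = vapply(st$bonds, `[[`, "", "sym"),
    stringsAsFactors = FALSE)
  if (nb) {
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key))
      stop("SMILES parse error: duplicate bond between an atom pair", call. = FALSE)
  }

  # provisional aromatic bonds: unspecified or ':' between two aromatic atoms
  arom_bond <- logical(nb)
  order <- integer(nb)
  for (k in seq_len(nb)) {
    sym <- bonds$sym[k]
    both_arom <- atoms$aromatic[bonds$i[k]] && atoms$aromatic[bonds$j[k]]
    if (sym %in% c("", ":") && both_arom) {
      arom_bond[k] <- TRUE
      order[k] <- 1L  # provisional; kekulization may raise to 2
    } else {
      order[k] <- switch(sym, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 1L, 1L)
    }
  }

  # aromatic bonds that are bridges (not in any ring) are plain single bonds,
  # e.g. the inter-ring bond of biphenyl written without '-'
  if (any(arom_bond)) {
    g <- igraph::graph_from_data_frame(bonds[, c("i", "j")], directed = FALSE,
                                       vertices = data.frame(name = seq_len(na)))
    br <- as.integer(igraph::bridges(g))
    arom_bond[br[br <= nb]] <- FALSE
  }

  kek <- .kekulize(atoms, bonds, order, arom_bond, text)
  order <- kek$order

  # fill implicit hydrogens for organic-subset atoms (hcount NA)
  bsum <- integer(na)
  for (k in seq_len(nb)) {
    bsum[bonds$i[k]] <- bsum[bonds$i[k]] + order[k]
    bsum[bonds$j[k]] <- bsum[bonds$j[k]] + order[k]
  }
  for (a in seq_len(na)) {
    if (!is.na(atoms$hcount[a])) next
    targets <- .standard_valences[[atoms$element[a]]]
    fit <- targets[targets >= bsum[a]]
    atoms$hcount[a] <- if (length(fit)) min(fit) - bsum[a] else 0L
  }

  mol <- molecular_graph(
    atoms = atoms,
    bonds = data.frame(i = bonds$i, j = bonds$j, order = order,
                       aromatic = arom_bond)[seq_len(nb), , drop = FALSE],
    id = id)
  mol
}

# Assign alternating single/double bonds within aromatic systems via a
# backtracking perfect matching.  Atoms that must carry exactly one ring
# double bond: aromatic C (uncharged, no exocyclic multiple bond) and
# aromatic N/P with no hydrogen and no negative charge.  Aromatic O, S,
# [nH]-type N and anions contribute lone pairs instead.
.kekulize <- function(atoms, bonds, order, arom_bond, text) {
  if (!any(arom_bond)) return(list(order = order))
  na <- nrow(atoms)
  exo_multiple <- logical(na)
  for (k in seq_len(nrow(bonds))) {
    if (!arom_bond[k] && order[k] >= 2L) {
      exo_multiple[bonds$i[k]] <- TRUE
      exo_multiple[bonds$j[k]] <- TRUE
    }
  }
  needs <- rep(FALSE, na)
  for (a in seq_len(na)) {
    if (!atoms$aromatic[a]) next
    el <- atoms$element[a]
    h <- atoms$hcount[a]
    h <- if (is.na(h)) 0L else h
    if (exo_multiple[a] || atoms$charge[a] < 0L) next
    if (el == "C") needs[a] <- TRUE
    else if (el %in% c("N", "P") && h == 0L) needs[a] <- TRUE
  }
  # adjacency over aromatic ring bonds, keyed by atom
  cand <- which(arom_bond)
  adj <- vector("list", na)
  for (k in cand) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], k)
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], k)
  }
  matched <- integer(na)  # bond index carrying this atom's double bond
  todo <- which(needs)
  assign_next <- function(pos) {
    while (pos <= length(todo) && matched[todo[pos]] > 0L) pos <- pos + 1L
    if (pos > length(todo)) return(TRUE)
    a <- todo[pos]
    for (k in adj[[a]]) {
      b <- if (bonds$i[k] == a) bonds$j[k] else bonds$i[k]
      if (!needs[b] || matched[b] > 0L) next
      matched[a] <<- k; matched[b] <<- k
      if (assign_next(pos + 1L)) return(TRUE)
      matched[a] <<- 0L; matched[b] <<- 0L
    }
    FALSE
  }
  if (!assign_next(1L))
    stop(sprintf("SMILES parse error: cannot Kekulize aromatic system in '%s'",
                 text), call. = FALSE)
  dbl <- unique(matched[matched > 0L])
  order[dbl] <- 2L
  list(order = order)
}

#' Read molecules from a SMILES file
#'
#' One molecule per line: a SMILES string optionally followed by whitespace
#' (tab or spaces) and an identifier.  Blank lines and lines starting with
#' `#` are skipped.
#'
#' @param path file path.
#' @return list of [molecular_graph()] objects.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], "[ \t]+")[[1]]
    id <- if (length(parts) >= 2L) parts[2L] else paste0("mol", k)
    out[[k]] <- tryCatch(parse_smiles(parts[1L], id = id),
                         error = function(e)
                           stop(sprintf("line %d (%s): %s", k, id,
                                        conditionMessage(e)), call. = FALSE))
  }
  out
}
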