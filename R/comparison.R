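#' Priority order of scored fragments
#'
#' Stable ranking of identifiers by a score, with tie groups: consecutive
#' entries whose scores differ by less than `tolerance` are joined with
#' an approximate-equality sign in the formatted order.
#'
#' @param scores named numeric vector (names are ids).
#' @param larger_is_better direction of "better".
#' @param tolerance absolute score difference below which two entries tie.
#' @param metric label for printing.
#' @return object of class `priority_order`: list with `metric`, `ids`,
#'   `scores` (sorted best-first), `groups` (list of tied id vectors) and
#'   `approximate` flag.
#' @examples
#' priority_order(c(`1W51` = 20.67, `2P83` = 21.47, `3L58` = 23.20))
#' @export
priority_order <- function(scores, larger_is_better = TRUE, tolerance = 0,
                           metric = "score") {
  if (length(scores) < 2L) stop("priority order needs at least two ids")
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("scores must be named by id")
  ord <- order(if (larger_is_better) -scores else scores)
  s <- scores[ord]
  groups <- list(names(s)[1L])
  for (k in seq_along(s)[-1L]) {
    if (abs(s[k] - s[k - 1L]) < tolerance)
      groups[[length(groups)]] <- c(groups[[length(groups)]], names(s)[k])
    else groups[[length(groups) + 1L]] <- names(s)[k]
  }
  structure(list(metric = metric, ids = names(s), scores = unname(s),
                 groups = groups, approximate = FALSE),
            class = "priority_order")
}

#' @export
format.priority_order <- function(x, ...) {
  paste(vapply(x$groups, paste, "", collapse = "≈"), collapse = ">")
}

#' @export
print.priority_order <- function(x, ...) {
  cat(sprintf("<priority order by %s%s: %s>\n", x$metric,
              if (x$approximate) " (approximate)" else "", format(x)))
  invisible(x)
}

# parse IC50 entries that may be point values ("11") or ranges ("15-80");
# returns a two-column lo/hi matrix in nM
parse_ic50 <- function(x) {
  x <- trimws(as.character(x))
  out <- t(vapply(x, function(v) {
    if (grepl("^[0-9.eE+]+-[0-9.eE+]+$", v)) {
      p <- as.numeric(strsplit(v, "-")[[1]])
      sort(p)
    } else {
      p <- suppressWarnings(as.numeric(v))
      if (is.na(p) || p <= 0) stop("invalid IC50 value: ", v)
      c(p, p)
    }
  }, numeric(2)))
  colnames(out) <- c("lo", "hi")
  out
}

#' Priority order from experimental IC50 values
#'
#' Smaller IC50 is better.  Entries may be ranges (`"15-80"`); an entry
#' strictly beats another only when its upper bound lies below the other's
#' lower bound.  When intervals overlap, midpoints decide and the order is
#' flagged approximate.
#'
#' @param ic50 named character or numeric vector of IC50s in nM.
#' @return a `priority_order` (scores are interval midpoints).
#' @export
ic50_priority_order <- function(ic50) {
  iv <- parse_ic50(ic50)
  mid <- (iv[, "lo"] + iv[, "hi"]) / 2
  names(mid) <- names(ic50)
  po <- priority_order(mid, larger_is_better = FALSE, metric = "IC50")
  ord <- match(po$ids, names(ic50))
  sep <- iv[ord, , drop = FALSE]
  overlap <- any(sep[-nrow(sep), "hi"] >= sep[-1L, "lo"])
  po$approximate <- overlap
  po
}

# attributed-graph isomorphism: vertex colors from element+charge, edge
# colors from bond order with aromatic ring bonds pooled (kekulization is
# not unique, so the two Kekule forms of a ring must compare equal)
mol_isomorphic <- function(a, b) {
  if (nrow(a$atoms) != nrow(b$atoms) || nrow(a$bonds) != nrow(b$bonds))
    return(FALSE)
  vkey <- function(m) paste(m$atoms$element, m$atoms$charge)
  keys <- unique(c(vkey(a), vkey(b)))
  ekey <- function(m) ifelse(m$bonds$aromatic, 0L, m$bonds$order)
  ga <- mol_igraph(a); gb <- mol_igraph(b)
  igraph::isomorphic(
    ga, gb, method = "vf2",
    vertex.color1 = match(vkey(a), keys), vertex.color2 = match(vkey(b), keys),
    edge.color1 = ekey(a) + 1L, edge.color2 = ekey(b) + 1L)
}

#' Detect constitutional isomers
#'
#' Groups molecules that share a molecular formula (implicit hydrogens
#' included) but differ in connectivity.  Exact duplicates (isomorphic
#' attributed graphs) are not isomers and are reported separately.
#'
#' @param mols list of `molecular_graph` objects.
#' @return list with `groups` (list of id vectors, each a set of mutually
#'   constitutional-isomeric molecules) and `duplicates` (list of id vectors
#'   of isomorphic repeats).
#' @export
detect_constitutional_isomers <- function(mols) {
  ids <- vapply(mols, function(m) m$id, "")
  formulas <- vapply(mols, molecular_formula, "")
  groups <- list()
  duplicates <- list()
  for (f in unique(formulas)) {
    members <- which(formulas == f)
    if (length(members) < 2L) next
    # partition members into isomorphism classes
    classes <- list()
    for (m in members) {
      placed <- FALSE
      for (ci in seq_along(classes)) {
        if (mol_isomorphic(mols[[m]], mols[[classes[[ci]][1L]]])) {
          classes[[ci]] <- c(classes[[ci]], m)
          placed <- TRUE
          break
        }
      }
      if (!placed) classes[[length(classes) + 1L]] <- m
    }
    for (cl in classes)
      if (length(cl) > 1L)
        duplicates[[length(duplicates) + 1L]] <- ids[cl]
    if (length(classes) > 1L)
      groups[[length(groups) + 1L]] <-
        ids[vapply(classes, `[`, 0L, 1L)]
  }
  list(groups = groups, duplicates = duplicates)
}

#' Default isostere substitution table
#'
#' Single-atom swaps regarded as classical isosteric replacements: the
#' pyrrole-type N-H of a five-membered aromatic ring against thiophene-type
#' sulfur, and aromatic C-H against pyridine-type nitrogen.
#'
#' @return list of substitution rules; each rule has a `name` and two sides
#'   `a`/`b` describing the swapped atom environment.
#' @export
default_isostere_table <- function() {
  list(
    list(name = "NH<->S (5-ring)",
         a = list(element = "N", aromatic = TRUE, min_h = 1L, ring5 = TRUE,
                  new_h = 0L),
         b = list(element = "S", aromatic = TRUE, min_h = 0L, ring5 = TRUE,
                  new_h = 0L)),
    list(name = "CH<->N (aromatic)",
         a = list(element = "C", aromatic = TRUE, min_h = 1L, ring5 = FALSE,
                  new_h = 0L),
         b = list(element = "N", aromatic = TRUE, min_h = 0L, ring5 = FALSE,
                  new_h = 1L)))
}

# atoms of mol matching one side of a substitution rule
.matching_atoms <- function(mol, side, in5) {
  which(mol$atoms$element == side$element &
          mol$atoms$aromatic == side$aromatic &
          mol$atoms$hcount >= side$min_h &
          (!side$ring5 | in5))
}

# swap atom `a` of mol to the `to` side of a rule
.apply_swap <- function(mol, a, to) {
  mol$atoms$element[a] <- to$element
  mol$atoms$hcount[a] <- to$new_h
  mol
}

#' Pair isosteric molecules
#'
#' Finds unordered pairs of molecules whose attributed graphs become
#' isomorphic after exactly one substitution from the table, in either
#' direction.
#'
#' @param mols list of `molecular_graph` objects.
#' @param substitution_table from [default_isostere_table()] (extensible).
#' @return data.frame with columns `id1`, `id2`, `rule`.
#' @export
pair_isosteres <- function(mols, substitution_table = default_isostere_table()) {
  ids <- vapply(mols, function(m) m$id, "")
  in5 <- lapply(mols, .atoms_in_aromatic_5ring)
  out <- data.frame(id1 = character(), id2 = character(), rule = character(),
                    stringsAsFactors = FALSE)
  nm <- length(mols)
  if (nm < 2L) return(out)
  hac <- vapply(mols, heavy_atom_count, 0L)
  for (p in seq_len(nm - 1L)) {
    for (q in (p + 1L):nm) {
      if (hac[p] != hac[q]) next
      hit <- NULL
      for (rule in substitution_table) {
        for (dir in 1:2) {
          from <- if (dir == 1L) rule$a else rule$b
          to <- if (dir == 1L) rule$b else rule$a
          src <- mols[[p]]; dst <- mols[[q]]
          for (a in .matching_atoms(src, from, in5[[p]])) {
            if (mol_isomorphic(.apply_swap(src, a, to), dst)) {
              hit <- rule$name
              break
            }
          }
          if (!is.null(hit)) break
        }
        if (!is.null(hit)) break
      }
      if (!is.null(hit))
        out <- rbind(out, data.frame(id1 = ids[p], id2 = ids[q], rule = hit,
                                     stringsAsFactors = FALSE))
    }
  }
  out
}

#' Side-chain effect report
#'
#' Parent ligands sharing one scaffold differ only in their side chains;
#' docked fragments have those side chains removed.  The report juxtaposes
#' the experimental potency order of the parents with the BE, LE and BEI
#' orders of the shared-scaffold fragments and flags each fragment metric
#' whose order disagrees with experiment (tied ids count as unordered).
#'
#' @param parent_records data.frame with columns `id`, `ic50_nM`
#'   (values or ranges such as `"15-80"`).
#' @param fragment_scores data.frame from [score_fragments()] for the same
#'   ids.
#' @param le_tolerance tie tolerance on LE (default 0.005).
#' @return object of class `comparison_report`.
#' @export
side_chain_effect_report <- function(parent_records, fragment_scores,
                                     le_tolerance = 0.005) {
  if (nrow(parent_records) < 2L)
    stop("side-chain comparison needs at least two parent ligands")
  ids <- parent_records$id
  m <- match(ids, fragment_scores$id)
  if (anyNA(m))
    stop("missing fragment scores for: ", paste(ids[is.na(m)], collapse = ", "))
  fs <- fragment_scores[m, ]
  exp_order <- ic50_priority_order(stats::setNames(parent_records$ic50_nM, ids))
  orders <- list(
    BE = priority_order(stats::setNames(fs$delta_g, ids),
                        larger_is_better = FALSE, metric = "BE"),
    LE = priority_order(stats::setNames(fs$LE, ids), tolerance = le_tolerance,
                        metric = "LE"),
    BEI = priority_order(stats::setNames(fs$BEI, ids), metric = "BEI"))
  discordant <- vapply(orders, function(po)
    !identical(po$ids, exp_order$ids), TRUE)
  structure(list(ids = ids, relation = "parent_fragment",
                 experimental = exp_order, fragment_orders = orders,
                 discordant = discordant,
                 any_discordant = any(discordant)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<side-chain effect report>\n")
  cat(sprintf("  experimental (IC50): %s%s\n", format(x$experimental),
              if (x$experimental$approximate) " [approx]" else ""))
  for (nm in names(x$fragment_orders))
    cat(sprintf("  fragment %-4s: %s%s\n", nm, format(x$fragment_orders[[nm]]),
                if (x$discordant[[nm]]) "  << discordant" else ""))
  invisible(x)
}

#' Pairwise score comparison
#'
#' Deltas (first minus second) and per-metric winners for a pair of scored
#' fragments, used in isomer and isostere reports.  Deltas are antisymmetric
#' under swapping the pair.
#'
#' @param scores data.frame from [score_fragments()].
#' @param id1,id2 ids present in `scores`.
#' @param relation label (`"constitutional_isomers"`, `"isosteres"`, ...).
#' @return list with `pair`, `relation`, `deltas` (BE, LE, BEI) and
#'   `winners`.
#' @export
compare_pair <- function(scores, id1, id2, relation = "pair") {
  r1 <- scores[scores$id == id1, ]
  r2 <- scores[scores$id == id2, ]
  if (nrow(r1) != 1L || nrow(r2) != 1L) stop("ids must match exactly one row")
  deltas <- c(BE = r1$delta_g - r2$delta_g, LE = r1$LE - r2$LE,
              BEI = r1$BEI - r2$BEI)
  winners <- c(BE = if (deltas[["BE"]] < 0) id1 else id2,  # lower BE better
               LE = if (deltas[["LE"]] > 0) id1 else id2,
               BEI = if (deltas[["BEI"]] > 0) id1 else id2)
  list(pair = c(id1, id2), relation = relation, deltas = deltas,
       winners = winners)
}
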