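# Brute-force VF-style graph isomorphism oracle, independent of both the
# package's hashing route and igraph: depth-first vertex matching over
# adjacency matrices with degree pruning.  Feasible up to ~12 nodes.
oracle_isomorphic <- function(nA, edgesA, nB, edgesB) {
  if (nA != nB || nrow(edgesA) != nrow(edgesB)) return(FALSE)
  adj <- function(n, e) {
    m <- matrix(FALSE, n, n)
    for (k in seq_len(nrow(e))) {
      m[e[k, 1], e[k, 2]] <- TRUE
      m[e[k, 2], e[k, 1]] <- TRUE
    }
    m
  }
  A <- adj(nA, edgesA)
  B <- adj(nB, edgesB)
  degA <- rowSums(A)
  degB <- rowSums(B)
  if (!identical(sort(degA), sort(degB))) return(FALSE)
  map <- integer(nA)  # map[a] = matched vertex of B, 0 if free
  used <- logical(nB)
  match_from <- function(a) {
    if (a > nA) return(TRUE)
    for (b in which(!used & degB == degA[a])) {
      ok <- TRUE
      for (a2 in seq_len(a - 1L)) {
        if (A[a, a2] != B[b, map[a2]]) { ok <- FALSE; break }
      }
      if (!ok) next
      map[a] <<- b; used[b] <<- TRUE
      if (match_from(a + 1L)) return(TRUE)
      map[a] <<- 0L; used[b] <<- FALSE
    }
    FALSE
  }
  match_from(1L)
}

# Random undirected simple graph as an edge matrix; connectivity not forced.
random_graph <- function(n, p = 0.35) {
  pairs <- t(combn(n, 2))
  sel <- stats::runif(nrow(pairs)) < p
  list(n = n, edges = pairs[sel, , drop = FALSE])
}

# Random permutation of a graph's vertex labels.
permute_graph <- function(g) {
  perm <- sample(g$n)
  e <- g$edges
  if (nrow(e)) e <- cbind(perm[e[, 1]], perm[e[, 2]])
  list(n = g$n, edges = e)
}

# V2000 MOL block for benzene (Kekulized), used for SDF reader tests.
benzene_molblock <- function(title = "benzene") {
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s0  0  0  0  0  0  0  0  0  0  0  0",
                   c(0, 1.2, 2.4, 2.4, 1.2, 0), c(0, 0, 1, 2.4, 3.4, 2.4),
                   0, "C")
  bonds <- sprintf("%3d%3d%3d  0", c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 1),
                   c(1, 2, 1, 2, 1, 2))
  c(title, "  fragrank", "",
    "  6  6  0  0  0  0  0  0  0  0999 V2000", atoms, bonds, "M  END")
}

table4_inputs <- function() {
  tabs <- bace1_reference_tables()
  iso <- tabs$isophthalamide
  desc <- tabs$descriptors
  m <- match(iso$pdb, desc$pdb)
  list(
    records = data.frame(id = iso$pdb, delta_g = iso$BE,
                         ic50_nM = iso$ic50_nM, stringsAsFactors = FALSE),
    descriptors = data.frame(id = iso$pdb, HAC = desc$HAC_fragment[m],
                             MW = desc$MW_fragment[m],
                             stringsAsFactors = FALSE),
    printed = iso)
}
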