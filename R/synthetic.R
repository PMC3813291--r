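#' Default molecule-assembly template set
#'
#' Ring systems, linkers and side chains from which the synthetic generator
#' assembles molecules, echoing the scaffold families common among small
#' aspartyl-protease inhibitors (aryl and fused-aryl rings, piperazine,
#' pyrimidinone; methylene and amide linkers; small polar/apolar side
#' chains).  Each template carries an additive binding-energy contribution
#' in kcal/mol; assembled molecules sum their templates' terms, so the
#' generated energies fall in the band typical of docked fragments (about
#' -2 to -12 kcal/mol).
#'
#' @return list with elements `rings`, `linkers`, `side_chains`; each entry
#'   has `name`, `smiles`, `energy`, and for linkers the attachment atom
#'   indices `ends`.
#' @export
default_template_spec <- function() {
  list(
    rings = list(
      list(name = "benzene", smiles = "c1ccccc1", energy = -1.8),
      list(name = "pyridine", smiles = "c1ccncc1", energy = -2.0),
      list(name = "fused_bicycle", smiles = "c1ccc2ncccc2c1", energy = -3.1),
      list(name = "pyrimidinone", smiles = "O=C1C=CN=CN1", energy = -2.6),
      list(name = "piperazine", smiles = "C1CNCCN1", energy = -2.2)),
    linkers = list(
      list(name = "methylene", smiles = "C", ends = c(1L, 1L), energy = -0.3),
      list(name = "ethylene", smiles = "CC", ends = c(1L, 2L), energy = -0.4),
      list(name = "amide", smiles = "CC(=O)N", ends = c(1L, 4L), energy = -1.1)),
    side_chains = list(
      list(name = "methyl", smiles = "C", energy = -0.2),
      list(name = "hydroxyl", smiles = "O", energy = -0.5),
      list(name = "amino", smiles = "N", energy = -0.4),
      list(name = "methoxy", smiles = "OC", energy = -0.3),
      list(name = "acetamide_chain", smiles = "CC(=O)N", energy = -0.9)))
}

# run expr with a private RNG stream seeded by `seed`
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# parse a template once, attaching its ground-truth roles:
# cycle atoms are RING; exocyclic atoms of a ring template are SIDE_CHAIN
# (e.g. the pyrimidinone carbonyl oxygen); linker/side-chain templates get
# a single role for all atoms
.parse_template <- function(tpl, class) {
  mol <- parse_smiles(tpl$smiles, id = tpl$name)
  roles <- switch(class,
    ring = {
      systems <- perceive_ring_systems(mol)
      r <- rep("SIDE_CHAIN", nrow(mol$atoms))
      r[unlist(lapply(systems, `[[`, "atoms"))] <- "RING"
      r
    },
    linker = rep("LINKER", nrow(mol$atoms)),
    side_chain = rep("SIDE_CHAIN", nrow(mol$atoms)))
  list(name = tpl$name, mol = mol, roles = roles, energy = tpl$energy,
       ends = tpl$ends)
}

# append template atoms/bonds to an assembly; returns new assembly and the
# index offset of the appended atoms
.append_template <- function(asm, tmol, roles, template) {
  off <- if (is.null(asm$atoms)) 0L else nrow(asm$atoms)
  b <- tmol$bonds
  if (nrow(b)) { b$i <- b$i + off; b$j <- b$j + off }
  asm$atoms <- rbind(asm$atoms, tmol$atoms)
  asm$bonds <- rbind(asm$bonds, b)
  asm$roles <- c(asm$roles, roles)
  asm$template <- c(asm$template, rep(template, nrow(tmol$atoms)))
  asm$offset <- off
  asm
}

# bond two assembly atoms with a single bond, consuming one implicit H each
.join_atoms <- function(asm, a, b) {
  if (asm$atoms$hcount[a] < 1L || asm$atoms$hcount[b] < 1L)
    stop(sprintf(
      "template rejected: no free valence at attachment atom %d or %d", a, b))
  asm$atoms$hcount[a] <- asm$atoms$hcount[a] - 1L
  asm$atoms$hcount[b] <- asm$atoms$hcount[b] - 1L
  asm$bonds <- rbind(asm$bonds,
                     data.frame(i = a, j = b, order = 1L, aromatic = FALSE))
  asm
}

# ring atoms of assembly unit `u` that still have a free hydrogen
.free_ring_atoms <- function(asm, u) {
  which(asm$unit == u & asm$roles == "RING" & asm$atoms$hcount >= 1L)
}

# sample one element from a vector (safe for length-1 vectors)
.pick1 <- function(x) x[sample.int(length(x), 1L)]

#' Generate a synthetic molecule library with ground truth
#'
#' Assembles `n` molecules by sampling 1-3 ring-system templates, joining
#' consecutive rings with linker templates and decorating ring atoms with
#' 0-4 side chains.  Atom roles, source template names and the additive
#' energy sum are recorded at assembly time, giving an exact ground truth
#' against which dissection can be validated.  Fully reproducible for a
#' fixed seed; the global RNG state is left untouched.
#'
#' @param n number of molecules (>= 1).
#' @param seed integer seed.
#' @param spec template set, see [default_template_spec()].
#' @return list with `mols` (list of `molecular_graph`) and `truth` (list
#'   per molecule: `id`, `roles`, `templates`, `true_energy`).
#' @export
generate_library <- function(n, seed = 1L, spec = default_template_spec()) {
  stopifnot(n >= 1L, length(spec$rings) > 0L)
  rings <- lapply(spec$rings, .parse_template, class = "ring")
  linkers <- lapply(spec$linkers, .parse_template, class = "linker")
  chains <- lapply(spec$side_chains, .parse_template, class = "side_chain")
  .with_seed(seed, {
    mols <- vector("list", n)
    truth <- vector("list", n)
    for (m in seq_len(n)) {
      k_rings <- sample(1:3, 1L)
      asm <- list(atoms = NULL, bonds = NULL, roles = character(),
                  template = character(), unit = integer())
      used <- character()
      energy <- 0
      prev_unit <- 0L
      for (r in seq_len(k_rings)) {
        rt <- rings[[.pick1(seq_along(rings))]]
        asm <- .append_template(asm, rt$mol, rt$roles, rt$name)
        asm$unit <- c(asm$unit, rep(r, nrow(rt$mol$atoms)))
        used <- c(used, rt$name)
        energy <- energy + rt$energy
        if (r > 1L) {
          lt <- linkers[[.pick1(seq_along(linkers))]]
          ring_a <- .free_ring_atoms(asm, r - 1L)
          ring_b <- .free_ring_atoms(asm, r)
          if (!length(ring_a) || !length(ring_b))
            stop("template rejected: no free valence left on a ring system")
          la <- .append_template(asm, lt$mol, lt$roles, lt$name)
          la$unit <- c(la$unit, rep(0L, nrow(lt$mol$atoms)))
          la <- .join_atoms(la, .pick1(ring_a), la$offset + lt$ends[1L])
          la <- .join_atoms(la, .pick1(ring_b), la$offset + lt$ends[2L])
          asm <- la
          used <- c(used, lt$name)
          energy <- energy + lt$energy
        }
      }
      n_side <- sample(0:4, 1L)
      for (s in seq_len(n_side)) {
        anchor_pool <- which(asm$roles == "RING" & asm$atoms$hcount >= 1L)
        if (!length(anchor_pool)) break
        ct <- chains[[.pick1(seq_along(chains))]]
        sa <- .append_template(asm, ct$mol, ct$roles, ct$name)
        sa$unit <- c(sa$unit, rep(0L, nrow(ct$mol$atoms)))
        sa <- .join_atoms(sa, .pick1(anchor_pool), sa$offset + 1L)
        asm <- sa
        used <- c(used, ct$name)
        energy <- energy + ct$energy
      }
      id <- sprintf("SYN%04d", m)
      mols[[m]] <- molecular_graph(asm$atoms, asm$bonds, id = id)
      truth[[m]] <- list(id = id, roles = asm$roles, templates = used,
                         true_energy = energy)
    }
    list(mols = mols, truth = truth)
  })
}

#' Simulate binding records from ground-truth energies
#'
#' Adds Gaussian noise to the additive template energy of each molecule and
#' clamps the result to stay below zero (a docked pose is always reported as
#' at least marginally favorable).
#'
#' @param truth ground-truth list from [generate_library()].
#' @param noise_sd standard deviation of the noise in kcal/mol (>= 0).
#' @param seed integer seed.
#' @return data.frame with columns `id`, `delta_g`, `source`.
#' @export
simulate_binding <- function(truth, noise_sd = 0.25, seed = 1L) {
  stopifnot(noise_sd >= 0)
  .with_seed(seed, {
    dg <- vapply(truth, `[[`, 0, "true_energy") +
      stats::rnorm(length(truth), 0, noise_sd)
    dg <- pmin(dg, -0.01)
    data.frame(id = vapply(truth, `[[`, "", "id"), delta_g = dg,
               source = "simulated", stringsAsFactors = FALSE)
  })
}

#' Template indicator counts for a generated library
#'
#' One row per molecule, one column per template name, entries counting how
#' often the template was used — the design matrix for recovering the
#' additive energy terms by ordinary least squares.
#'
#' @param truth ground-truth list from [generate_library()].
#' @param spec the template set used for generation.
#' @return integer matrix with rownames = molecule ids.
#' @export
template_count_matrix <- function(truth, spec = default_template_spec()) {
  all_names <- c(vapply(spec$rings, `[[`, "", "name"),
                 vapply(spec$linkers, `[[`, "", "name"),
                 vapply(spec$side_chains, `[[`, "", "name"))
  mat <- t(vapply(truth, function(tr)
    vapply(all_names, function(nm) sum(tr$templates == nm), 0L),
    integer(length(all_names))))
  rownames(mat) <- vapply(truth, `[[`, "", "id")
  mat
}

#' True additive energy terms of a template set
#' @param spec template set.
#' @return named numeric vector (kcal/mol), in the column order of
#'   [template_count_matrix()].
#' @export
template_energies <- function(spec = default_template_spec()) {
  tpls <- c(spec$rings, spec$linkers, spec$side_chains)
  stats::setNames(vapply(tpls, `[[`, 0, "energy"),
                  vapply(tpls, `[[`, "", "name"))
}
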