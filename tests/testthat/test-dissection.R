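test_that("ring systems merge fused and spiro cycles but not bonded rings", {
  biphenyl <- perceive_ring_systems(parse_smiles("c1ccccc1-c1ccccc1"))
  expect_length(biphenyl, 2)
  expect_equal(vapply(biphenyl, function(s) length(s$atoms), 0L), c(6L, 6L))

  quin <- perceive_ring_systems(parse_smiles("c1ccc2ncccc2c1"))
  expect_length(quin, 1)
  expect_length(quin[[1]]$atoms, 10)
  expect_equal(quin[[1]]$n_rings, 2L)

  spiro <- perceive_ring_systems(parse_smiles("C1CCC2(C1)CCCCC2"))
  expect_length(spiro, 1)
  expect_length(spiro[[1]]$atoms, 10)

  expect_length(perceive_ring_systems(parse_smiles("CCCC")), 0)
})

test_that("atom roles partition into ring, linker and side chain", {
  # diphenylmethane: the CH2 carbon is the unique connecting path
  dpm <- parse_smiles("c1ccccc1Cc1ccccc1")
  roles <- classify_atoms(dpm)
  expect_equal(sum(roles == "LINKER"), 1L)
  expect_equal(roles[7], "LINKER")

  # benzanilide: carbonyl C, N and the =O are all linker atoms
  # (functional groups on the linker path are retained, not eliminated)
  ba <- parse_smiles("c1ccccc1C(=O)Nc1ccccc1")
  roles <- classify_atoms(ba)
  expect_equal(sum(roles == "LINKER"), 3L)
  expect_setequal(which(roles == "LINKER"), 7:9)

  # toluene: one ring system, no linkers possible
  expect_equal(classify_atoms(parse_smiles("Cc1ccccc1"))[1], "SIDE_CHAIN")

  # branches off a linker joined by single bonds are side chains
  br <- parse_smiles("c1ccccc1C(CC)Cc1ccccc1")
  roles <- classify_atoms(br)
  expect_equal(sum(roles == "LINKER"), 2L)
  expect_equal(sum(roles == "SIDE_CHAIN"), 2L)

  # partition is exhaustive and exclusive on every input
  for (smi in c("Cc1ccccc1", "c1ccccc1CCc1ccncc1", "CC(=O)c1ccccc1", "C1CCCCC1"))
    expect_true(all(classify_atoms(parse_smiles(smi)) %in%
                      c("RING", "LINKER", "SIDE_CHAIN")))
})

test_that("scaffold keeps rings and linkers, repairs cut-point valence", {
  tol <- parse_smiles("Cc1ccccc1", id = "toluene")
  scaf <- extract_scaffold(tol)
  expect_equal(nrow(scaf$atoms), 6L)
  expect_equal(sum(scaf$atoms$pi_marker), 0L)
  expect_equal(molecular_formula(scaf), "C6H6")

  # acetophenone: one ring system means no linkers, so the whole acetyl
  # group is side chain and the scaffold is bare benzene
  aceto <- extract_scaffold(parse_smiles("CC(=O)c1ccccc1"))
  expect_equal(molecular_formula(aceto), "C6H6")

  # exocyclic double bond cut leaves a dot pair, not a hydrogen
  cyhexone <- parse_smiles("O=C1CCCCC1")
  scaf <- extract_scaffold(cyhexone)
  expect_equal(nrow(scaf$atoms), 6L)
  expect_equal(sum(scaf$atoms$pi_marker), 1L)
  carbonyl <- which(scaf$atoms$pi_marker == 1L)
  expect_equal(scaf$atoms$hcount[carbonyl], 0L)
  expect_length(mol_valence_violations(scaf), 0)

  # single-bond cut to an unsaturated side chain leaves no dot pair
  styrene <- extract_scaffold(parse_smiles("C=Cc1ccccc1"))
  expect_equal(sum(styrene$atoms$pi_marker), 0L)
  expect_equal(molecular_formula(styrene), "C6H6")

  expect_error(dissect_molecule(parse_smiles("CCO", id = "ethanol")),
               "acyclic")
})

test_that("scaffold never gains atoms; equality iff no side chains", {
  lib <- generate_library(40, seed = 5)
  for (k in seq_along(lib$mols)) {
    mol <- lib$mols[[k]]
    scaf <- extract_scaffold(mol)
    expect_lte(heavy_atom_count(scaf), heavy_atom_count(mol))
    expect_lte(molecular_weight(scaf), molecular_weight(mol) + 1e-9)
    has_side <- any(lib$truth[[k]]$roles == "SIDE_CHAIN")
    expect_identical(heavy_atom_count(scaf) == heavy_atom_count(mol),
                     !has_side)
  }
})

test_that("frameworks ignore atom types and bond orders", {
  quin <- dissect_molecule(parse_smiles("c1ccc2ncccc2c1", id = "quin"))
  isoq <- dissect_molecule(parse_smiles("c1ccc2cnccc2c1", id = "isoq"))
  expect_equal(quin$framework$hash, isoq$framework$hash)
  # but the scaffolds differ as attributed graphs
  expect_false(fragrank:::mol_isomorphic(quin$scaffold, isoq$scaffold))

  # heteroatom mutation inside scaffolds never changes the framework
  set.seed(31)
  lib <- generate_library(30, seed = 13)
  for (mol in lib$mols) {
    h <- dissect_molecule(mol)$framework$hash
    mut <- mol
    flip <- sample(nrow(mut$atoms), max(1, nrow(mut$atoms) %/% 4))
    mut$atoms$element[flip] <- "N"
    mut$atoms$hcount[flip] <- pmax(0L, mut$atoms$hcount[flip] - 1L)
    expect_identical(dissect_molecule(mut)$framework$hash, h)
  }
})

test_that("framework grouping partitions ids deterministically", {
  mols <- list(parse_smiles("c1ccc2ncccc2c1", id = "quinoline"),
               parse_smiles("c1ccc2cnccc2c1", id = "isoquinoline"),
               parse_smiles("c1ccc2ccccc2c1", id = "naphthalene"))
  grp <- group_by_framework(mols)
  expect_equal(nrow(grp), 1L)
  expect_equal(grp$count, 3L)

  grp2 <- group_by_framework(list(parse_smiles("c1ccccc1", id = "benzene"),
                                  parse_smiles("c1ccccc1-c1ccccc1",
                                               id = "biphenyl")))
  expect_equal(nrow(grp2), 2L)

  # three hand-built template families -> exactly three groups, ordered by
  # descending member count
  fam <- list(parse_smiles("c1ccccc1", id = "a1"),
              parse_smiles("Cc1ccncc1", id = "a2"),
              parse_smiles("Oc1ccccc1C", id = "a3"),
              parse_smiles("c1ccc2ncccc2c1", id = "b1"),
              parse_smiles("Cc1ccc2ccccc2c1", id = "b2"),
              parse_smiles("C1CCC2(C1)CCCCC2", id = "c1"))
  grp3 <- group_by_framework(fam)
  expect_equal(nrow(grp3), 3L)
  expect_equal(grp3$count, c(3L, 2L, 1L))
  expect_equal(attr(grp3, "groups")[[1]], c("a1", "a2", "a3"))
})
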