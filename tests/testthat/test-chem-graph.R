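test_that("SMILES parsing fills implicit hydrogens by standard valence", {
  b <- parse_smiles("c1ccccc1")
  expect_equal(nrow(b$atoms), 6L)
  expect_equal(b$atoms$hcount, rep(1L, 6))
  expect_true(all(b$atoms$aromatic))

  q <- parse_smiles("c1ccc2ncccc2c1")
  expect_equal(nrow(q$atoms), 10L)
  expect_equal(sum(q$atoms$element == "N"), 1L)
  expect_equal(molecular_formula(q), "C9H7N")

  m <- parse_smiles("C1CC1C(=O)O")
  expect_equal(nrow(m$atoms), 6L)
  # carboxyl: carbonyl O bears no H, hydroxyl O bears one
  o_h <- m$atoms$hcount[m$atoms$element == "O"]
  expect_equal(sort(o_h), c(0L, 1L))

  # charged bracket atom
  n4 <- parse_smiles("C[N+](C)(C)C")
  expect_equal(n4$atoms$charge[n4$atoms$element == "N"], 1L)
  expect_equal(n4$atoms$hcount[n4$atoms$element == "N"], 0L)
})

test_that("malformed SMILES report the offending position, bad elements named", {
  expect_error(parse_smiles("C(C"), "unclosed '\\('")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("CC)C"), "position 3")
  expect_error(parse_smiles("C[Xq]C"), "unsupported element")
  expect_error(parse_smiles("CJC"), "unsupported element")
  expect_error(parse_smiles(""), "non-empty")
})

test_that("parsed valences agree with bond orders and hydrogen totals", {
  fixture <- c("c1ccccc1", "c1ccc2ncccc2c1", "c1ccc2[nH]cnc2c1", "CC(=O)Nc1ccccc1",
               "C1CC1C(=O)O", "c1ccncc1", "C1CNCCN1", "O=C1C=CN=CN1",
               "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "c1cc[nH]c1", "c1ccsc1")
  for (smi in fixture) {
    mol <- parse_smiles(smi)
    expect_length(mol_valence_violations(mol), 0)
    # handshake: sum of per-atom bond orders is twice the bond-order total
    expect_equal(sum(mol_bond_order_sum(mol)), 2L * sum(mol$bonds$order))
  }
})

test_that("parsed formulas and weights match an external toolkit oracle", {
  smis <- c("c1ccccc1", "c1ccc2ncccc2c1", "C1CC1C(=O)O", "CC(=O)Nc1ccccc1",
            "c1cc[nH]c1", "c1ccsc1", "O=C1C=CN=CN1")
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smis, paste0("m", seq_along(smis))))
  mf <- ChemmineR::MF(sdf, addH = TRUE)
  mw <- ChemmineR::MW(sdf, addH = TRUE)
  for (k in seq_along(smis)) {
    mol <- parse_smiles(smis[k])
    expect_equal(molecular_formula(mol), unname(mf[k]))
    expect_lt(abs(molecular_weight(mol) - mw[k]), 0.15)
  }
})

test_that("SDF records become graphs with hydrogens folded", {
  one <- tempfile(fileext = ".sdf")
  writeLines(c(benzene_molblock(), "$$$$"), one)
  mols <- read_sdf(one)
  expect_length(mols, 1)
  expect_equal(nrow(mols[[1]]$atoms), 6L)
  expect_equal(mols[[1]]$atoms$hcount, rep(1L, 6))

  two <- tempfile(fileext = ".sdf")
  writeLines(c(benzene_molblock("a"), "$$$$", benzene_molblock("b"), "$$$$"),
             two)
  expect_length(read_sdf(two), 2)

  empty <- tempfile(fileext = ".sdf")
  file.create(empty)
  expect_warning(res <- read_sdf(empty), "empty")
  expect_length(res, 0)
})

test_that("anonymization drops attributes but keeps topology", {
  quin <- anonymize(parse_smiles("c1ccc2ncccc2c1"))
  isoq <- anonymize(parse_smiles("c1ccc2cnccc2c1"))
  expect_equal(quin$hash, isoq$hash)  # same fused 6-6 skeleton

  expect_equal(anonymize(parse_smiles("c1ccccc1"))$hash,
               anonymize(parse_smiles("C1CCCCC1"))$hash)

  expect_false(anonymize(parse_smiles("c1ccccc1"))$hash ==
                 anonymize(parse_smiles("Cc1ccncc1"))$hash)
})

test_that("canonical hash is deterministic and relabel-invariant", {
  set.seed(42)
  for (rep in 1:25) {
    g <- random_graph(sample(4:12, 1))
    h1 <- anonymous_graph(g$n, g$edges)$hash
    expect_identical(h1, anonymous_graph(g$n, g$edges)$hash)
    gp <- permute_graph(g)
    expect_identical(h1, anonymous_graph(gp$n, gp$edges)$hash)
  }
  # path P4 vs star S4: same size and edge count, different degree sequence
  p4 <- anonymous_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
  s4 <- anonymous_graph(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_false(p4$hash == s4$hash)
})

test_that("hash equality coincides with brute-force isomorphism on a library", {
  set.seed(7)
  lib <- replicate(30, random_graph(sample(5:10, 1)), simplify = FALSE)
  hashes <- vapply(lib, function(g) anonymous_graph(g$n, g$edges)$hash, "")
  for (p in 1:(length(lib) - 1)) {
    for (q in (p + 1):length(lib)) {
      iso <- oracle_isomorphic(lib[[p]]$n, lib[[p]]$edges,
                               lib[[q]]$n, lib[[q]]$edges)
      expect_identical(hashes[p] == hashes[q], iso,
                       info = sprintf("pair %d-%d", p, q))
    }
  }
})

test_that("SMILES serialization round-trips structure and composition", {
  smis <- c("c1ccccc1", "c1ccc2ncccc2c1", "CC(=O)Nc1ccccc1", "C1CC1C(=O)O",
            "C[N+](C)(C)C", "c1cc[nH]c1", "C1CCC2(C1)CCCCC2")
  for (smi in smis) {
    m <- parse_smiles(smi)
    back <- parse_smiles(smiles_string(m))
    expect_equal(molecular_formula(back), molecular_formula(m))
    expect_identical(anonymize(back)$hash, anonymize(m)$hash)
    expect_equal(sort(back$atoms$element), sort(m$atoms$element))
  }
  lib <- generate_library(20, seed = 3)
  path <- tempfile(fileext = ".smi")
  write_smiles(lib$mols, path)
  back <- read_smiles(path)
  expect_equal(vapply(back, function(m) m$id, ""),
               vapply(lib$mols, function(m) m$id, ""))
  for (k in seq_along(back))
    expect_equal(molecular_formula(back[[k]]),
                 molecular_formula(lib$mols[[k]]))
})

test_that("framework hashes serialize to TSV", {
  path <- tempfile(fileext = ".tsv")
  mols <- list(parse_smiles("c1ccccc1", id = "bz"),
               parse_smiles("c1ccc2ncccc2c1", id = "quin"))
  df <- write_framework_hashes(mols, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back, df)
  expect_equal(back$id, c("bz", "quin"))
})
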