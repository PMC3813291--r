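test_that("priority orders sort stably and format with tie groups", {
  bei <- c(`1W51` = 20.67, `2P83` = 21.47, `3L58` = 23.20)
  po <- priority_order(bei, metric = "BEI")
  expect_equal(po$ids, c("3L58", "2P83", "1W51"))
  expect_equal(format(po), "3L58>2P83>1W51")

  # ids within tolerance join into a tie group
  le <- c(`2P83` = 0.391, `1W51` = 0.377, `3L58` = 0.377)
  po <- priority_order(le, tolerance = 0.005, metric = "LE")
  expect_equal(format(po), "2P83>1W51≈3L58")

  all_tied <- priority_order(c(a = 1, b = 1, c = 1), tolerance = 0.1)
  expect_length(all_tied$groups, 1)

  # idempotent: re-sorting the output changes nothing
  again <- priority_order(stats::setNames(po$scores, po$ids),
                          tolerance = 0.005, metric = "LE")
  expect_equal(again$ids, po$ids)
  expect_error(priority_order(c(a = 1)), "at least two")
})

test_that("IC50 orders handle ranges by interval and flag overlaps", {
  ord <- ic50_priority_order(c(`2P83` = "11", `3L58` = "15-80", `1W51` = "500"))
  expect_equal(ord$ids, c("2P83", "3L58", "1W51"))
  expect_equal(format(ord), "2P83>3L58>1W51")
  expect_false(ord$approximate)  # all intervals strictly separated

  overlapping <- ic50_priority_order(c(a = "10-100", b = "50", c = "900"))
  expect_true(overlapping$approximate)
  expect_error(ic50_priority_order(c(a = "0")), "invalid IC50")
})

test_that("constitutional isomer groups share a formula but not connectivity", {
  mols <- list(parse_smiles("c1ccc2ncccc2c1", id = "quinoline"),
               parse_smiles("c1ccc2cnccc2c1", id = "isoquinoline"),
               parse_smiles("CCCC", id = "butane"),
               parse_smiles("CC(C)C", id = "isobutane"),
               parse_smiles("CCCCC", id = "pentane"),
               parse_smiles("c1ccccc1", id = "bz1"),
               parse_smiles("c1ccccc1", id = "bz2"))
  res <- detect_constitutional_isomers(mols)
  expect_length(res$groups, 2)
  expect_true(any(vapply(res$groups, function(g)
    setequal(g, c("quinoline", "isoquinoline")), TRUE)))
  expect_true(any(vapply(res$groups, function(g)
    setequal(g, c("butane", "isobutane")), TRUE)))
  # isomorphic duplicates are not isomers
  expect_length(res$duplicates, 1)
  expect_setequal(res$duplicates[[1]], c("bz1", "bz2"))

  # grouping is independent of input order
  res_rev <- detect_constitutional_isomers(rev(mols))
  expect_equal(length(res_rev$groups), length(res$groups))
  sets <- lapply(res$groups, sort)
  sets_rev <- lapply(res_rev$groups, sort)
  expect_setequal(vapply(sets_rev, paste, "", collapse = "+"),
                  vapply(sets, paste, "", collapse = "+"))
})

test_that("isostere pairing finds single tabulated swaps in either direction", {
  mols <- list(parse_smiles("c1cc[nH]c1", id = "pyrrole"),
               parse_smiles("c1ccsc1", id = "thiophene"),
               parse_smiles("c1ccccc1", id = "benzene"),
               parse_smiles("c1ccncc1", id = "pyridine"),
               parse_smiles("Cc1ccccc1", id = "toluene"))
  pairs <- pair_isosteres(mols)
  key <- paste(pairs$id1, pairs$id2)
  expect_true("pyrrole thiophene" %in% key)
  expect_true("benzene pyridine" %in% key)
  expect_false(any(grepl("toluene", key)))  # different heavy atom count

  # symmetric under input order reversal
  pairs_rev <- pair_isosteres(rev(mols))
  expect_equal(nrow(pairs_rev), nrow(pairs))
})

test_that("side-chain reports flag discordant fragment orders", {
  t4 <- table4_inputs()
  sc <- score_fragments(t4$records, t4$descriptors)
  rep <- side_chain_effect_report(t4$records, sc)
  expect_equal(format(rep$experimental), "2P83>3L58>1W51")
  expect_equal(format(rep$fragment_orders$BE), "3L58>2P83>1W51")
  expect_true(rep$discordant[["BE"]])
  expect_true(rep$any_discordant)
  expect_error(side_chain_effect_report(t4$records[1, ], sc), "at least two")

  # concordant synthetic case: fragment scores aligned with potency
  parents <- data.frame(id = c("p1", "p2"), ic50_nM = c("10", "200"),
                        stringsAsFactors = FALSE)
  fs <- data.frame(id = c("p1", "p2"), delta_g = c(-9, -7),
                   pKi = delta_g_to_pki(c(-9, -7)),
                   LE = c(0.45, 0.35), BEI = c(22, 18))
  rep2 <- side_chain_effect_report(parents, fs)
  expect_false(rep2$any_discordant)

  # additive ground truth: discordance appears exactly when side-chain terms
  # invert the parent order relative to the shared-scaffold fragment
  frag_dg <- -6
  side <- c(p1 = -0.2, p2 = -2.5)           # parent potency order: p2 > p1
  parent_ic50 <- c(p1 = 300, p2 = 4)        # consistent with side chains
  fs3 <- data.frame(id = names(side), delta_g = c(frag_dg, frag_dg - 0.1),
                    pKi = delta_g_to_pki(c(frag_dg, frag_dg - 0.1)),
                    LE = c(0.30, 0.31), BEI = c(15, 15.5))
  rep3 <- side_chain_effect_report(
    data.frame(id = names(side), ic50_nM = as.character(parent_ic50)), fs3)
  expect_false(rep3$any_discordant)   # fragment order matches here
  fs3$delta_g <- rev(fs3$delta_g); fs3$LE <- rev(fs3$LE); fs3$BEI <- rev(fs3$BEI)
  rep4 <- side_chain_effect_report(
    data.frame(id = names(side), ic50_nM = as.character(parent_ic50)), fs3)
  expect_true(rep4$any_discordant)    # inverted fragment scores disagree
})

test_that("pairwise deltas are antisymmetric under swapping", {
  t4 <- table4_inputs()
  sc <- score_fragments(t4$records, t4$descriptors)
  ab <- compare_pair(sc, "1W51", "2P83", relation = "parent_fragment")
  ba <- compare_pair(sc, "2P83", "1W51", relation = "parent_fragment")
  expect_equal(ab$deltas, -ba$deltas)
  expect_equal(ab$winners[["BEI"]], "2P83")
})
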