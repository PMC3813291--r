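#' Packaged reference tables for the BACE-1 inhibitor set
#'
#' Two tables transcribed from the published analysis of 83 crystallographic
#' BACE-1 inhibitors and their dissected fragments:
#' * `descriptors` — per PDB code, heavy atom count, H-bond donor and
#'   acceptor counts and molecular weight, for the parent ligand and its
#'   fragment (83 rows);
#' * `isophthalamide` — the three isophthalamide-scaffold parents with
#'   experimental IC50 (nM, one entry a range), docked fragment binding
#'   energy (kcal/mol) and the published LE/BEI values.  The published LE of
#'   3L58 cannot be reproduced from its own BE and HAC (it repeats the 1W51
#'   value); that cell carries `le_erratum = TRUE` and is excluded from
#'   numeric checks.
#'
#' A lightweight checksum (row count plus fragment-MW column sum) guards
#' against accidental fixture corruption.
#'
#' @return list with data.frames `descriptors` and `isophthalamide`.
#' @export
bace1_reference_tables <- function() {
  dpath <- system.file("extdata", "bace1_descriptors.tsv", package = "fragrank",
                       mustWork = TRUE)
  ipath <- system.file("extdata", "bace1_isophthalamide.tsv",
                       package = "fragrank", mustWork = TRUE)
  desc <- utils::read.delim(dpath, stringsAsFactors = FALSE)
  iso <- utils::read.delim(ipath, stringsAsFactors = FALSE,
                           colClasses = c(ic50_nM = "character"))
  if (nrow(desc) != 83L || abs(sum(desc$MW_fragment) - 24226.0) > 0.05)
    stop("descriptor fixture checksum mismatch: file corrupted?")
  if (nrow(iso) != 3L || abs(sum(iso$BE) + 33.35) > 1e-9)
    stop("isophthalamide fixture checksum mismatch: file corrupted?")
  list(descriptors = desc, isophthalamide = iso)
}

#' Structures of identifiable reference fragments
#'
#' The handful of fragments in the reference descriptor table whose identity
#' is unambiguous from the text (benzene, quinoline, isoquinoline,
#' benzimidazole), parsed from packaged SMILES.
#'
#' @return list of `molecular_graph` objects with PDB-code ids.
#' @export
known_fragment_structures <- function() {
  path <- system.file("extdata", "known_fragments.smi", package = "fragrank",
                      mustWork = TRUE)
  read_smiles(path)
}
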