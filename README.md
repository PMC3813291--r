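# fragrank

Fragment dissection and ligand-efficiency indices for small-molecule
inhibitors.

In structure-based lead discovery, the raw docking or binding free energy
ΔG<sub>b</sub> of a molecule is a poor guide to which chemical *fragment* is
doing the work: bigger molecules bind more tightly simply because they have
more atoms. Two size-corrected indices fix this:

* **Ligand efficiency** — LE = −ΔG<sub>b</sub> / HAC, the binding free energy
  per heavy (non-hydrogen) atom;
* **Binding efficiency index** — BEI = pK<sub>i</sub> / MW(kDa), with
  pK<sub>i</sub> = −ΔG<sub>b</sub> / (ln 10 · R · T), which weights by
  molecular mass and so treats heteroatoms from lower rows of the periodic
  table (S, P, halogens) less generously than a per-atom count does.

`fragrank` implements the full analysis pipeline around these indices for a
set of inhibitors, as applied in fragment studies of BACE-1 (β-secretase)
ligands:

1. **Molecular graphs** — SMILES and SDF (V2000) input, implicit hydrogens by
   standard valence, internal Kekulization of aromatic rings.
2. **Hierarchical dissection** — every atom is classified as RING, LINKER
   (non-ring atoms on paths connecting ring systems, including their
   double-bonded appendages such as carbonyl oxygens) or SIDE_CHAIN. Rings
   plus linkers form the **scaffold** (simplified structure, with "dot pair"
   π markers where a double-bonded side chain was cut off); stripping all
   atom and bond attributes from the scaffold gives the **graph framework**,
   identified by a canonical, relabeling-invariant hash.
3. **Descriptors** — heavy atom count, molecular weight, H-bond donors and
   acceptors, rotatable bonds, plus the "10 or less rotatable bonds"
   selection gate applied to simplified structures.
4. **Efficiency scoring** — ΔG→pK<sub>i</sub> conversion (T = 298.15 K by
   default), LE, BEI, min–max normalized series and the per-fragment
   divergence ΔE = BEI<sub>norm</sub> − LE<sub>norm</sub>.
5. **Comparisons** — priority orders with tie groups, experimental IC50
   orders (ranges handled by interval), constitutional-isomer detection,
   isostere pairing (NH↔S in five-rings, CH↔N aromatic), and side-chain
   effect reports that flag when fragment-based orders contradict the
   experimental potency order of the parent ligands.
6. **Synthetic libraries** — molecules assembled from ring/linker/side-chain
   templates with recorded ground-truth atom roles and additive binding
   energies, for end-to-end validation of the dissection and scoring code.

Reference tables for 83 crystallographic BACE-1 inhibitors and their
fragments (descriptors, and the isophthalamide-scaffold IC50/binding-energy
triple) ship with the package under `inst/extdata/`.

## Worked example

Rescore the three isophthalamide-scaffold fragments from their tabulated
binding energies and fragment descriptors (HAC 28, MW 374.2 for all three):

```r
library(fragrank)
tabs <- bace1_reference_tables()
iso  <- tabs$isophthalamide
desc <- tabs$descriptors
m    <- match(iso$pdb, desc$pdb)

run <- run_pipeline(run_config("table",
  descriptors = data.frame(id = iso$pdb, HAC = desc$HAC_fragment[m],
                           MW = desc$MW_fragment[m]),
  records     = data.frame(id = iso$pdb, delta_g = iso$BE,
                           ic50_nM = iso$ic50_nM)))
print(run)
#> <fragrank pipeline run>
#>   mode: table; parsed 3, kept 3, discarded 0
#>   scored fragments: 3
#>   BE          : 3L58>2P83>1W51
#>   LE          : 3L58>2P83>1W51
#>   BEI         : 3L58>2P83>1W51
#>   experimental: 2P83>3L58>1W51

print(run$scores[, c("id", "delta_g", "pKi", "LE", "BEI")], digits = 4)
#>     id delta_g   pKi     LE   BEI
#> 1 1W51  -10.55 7.733 0.3768 20.67
#> 2 2P83  -10.96 8.034 0.3914 21.47
#> 3 3L58  -11.84 8.679 0.4229 23.19
```

The BEI column reproduces the published values (20.67, 21.47, 23.20 at the
printed precision), and the LE column the published 0.377 and 0.391 for
1W51 and 2P83. The experimental IC50 order (2P83 best) disagrees with every
fragment-based order — the fragments lack the side chains that differentiate
the parents — which `side_chain_effect_report()` flags as discordant. (The
published LE for 3L58 repeats the 1W51 value and is carried as a flagged
erratum in the fixture table; the value computed from its own BE and HAC is
0.423.)

Dissection works directly on structures:

```r
d <- dissect_molecule(parse_smiles("c1ccccc1C(=O)Nc1ccc(O)cc1", id = "example"))
print(d)
#> <dissection of example>
#>   atoms: 16 (12 ring, 3 linker, 1 side chain)
#>   ring systems: 2; scaffold: 15 atoms; framework hash: 15|1-15,2-6,...
smiles_string(d$scaffold)
#> [1] "C1=CC=CC=C1C(=O)NC2=CC=CC=C2"
```

The amide linker keeps its carbonyl oxygen (functional groups on linkers are
retained), while the phenolic OH — a side chain — is removed from the
scaffold.

A thin command-line wrapper over these functions is available at
`inst/scripts/fragrank.R` (subcommands `run`, `dissect`, `descriptors`,
`synth`).

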