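---
title: "Fragment dissection and efficiency indices: methods and design notes"
author: "fragrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment dissection and efficiency indices: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragrank)
```

## The analysis in one paragraph

Given a set of small-molecule inhibitors, `fragrank` dissects each structure
into ring systems, linkers and side chains; keeps rings plus linkers as the
*scaffold* (simplified structure) and its attribute-free topology as the
*graph framework*; computes size descriptors; converts binding free energies
to pK~i~; and scores each fragment with two size-corrected potency indices,

$$LE = \frac{-\Delta G_b}{HAC}, \qquad
  BEI = \frac{pK_i}{MW\,(\mathrm{kDa})}, \qquad
  pK_i = \frac{-\Delta G_b}{\ln 10 \cdot R\,T},$$

then ranks, normalizes and compares fragments: priority orders, isomer and
isostere pairings, and side-chain effect reports. The underlying assumption
throughout is additivity at the fragment level: that a scaffold's binding
contribution is meaningfully separable from its side chains', which is also
exactly what the synthetic validation data simulate.

## Molecular graphs

Molecules are stored as heavy-atom graphs with implicit hydrogen counts.
The SMILES parser covers the organic subset (B, C, N, O, P, S, F, Cl, Br, I),
brackets with charges and explicit H counts, branches and ring closures.
Three choices matter downstream:

* **Aromatic perception is notational.** Only rings *written* in aromatic
  (lowercase) form are flagged aromatic; no independent aromaticity model is
  applied. This keeps parsing predictable and is sufficient for fragment
  work, where inputs are curated strings.
* **Kekulization.** Aromatic rings are resolved internally to alternating
  single/double bonds by a backtracking perfect matching (aromatic C and
  pyridine-type N must carry exactly one ring double bond; O, S and
  pyrrole-type N-H contribute lone pairs). Every bond therefore has a
  definite order, which the scaffold definition requires, while the aromatic
  flag is retained for descriptor logic. A system that cannot be matched is
  rejected with an error rather than silently accepted.
* **Stereochemistry is parsed and discarded.** All structures in the
  motivating inhibitor set share one stereochemistry, and none of the
  computed quantities depend on it.

Hydrogen filling uses the smallest standard valence that accommodates the
bond-order sum (N 3/5, S 2/4/6, etc.). Atom indexing is 1-based throughout,
the native R convention; SDF input (delegated to ChemmineR, explicit
hydrogens folded) is converted on read.

## Dissection rules and their edge cases

*Ring systems.* Ring bonds are the non-bridge edges of the graph; ring
systems are connected components of the ring-bond subgraph. This merges
fused rings **and** spiro junctions (cycles sharing one atom) into a single
system — the literal reading of "cycles fused to other cycles form one unit
ring system" as atom-sharing — while rings joined only by a bond (biphenyl)
stay separate.

*Linkers.* Every connected component of non-ring atoms is necessarily a tree
(a cycle would have made its atoms ring atoms). If such a component touches
two or more ring systems, its linker core is the minimal subtree spanning
the attachment atoms, computed by pruning non-attachment leaves. Non-ring
atoms attached to a core atom by a double or triple bond are then pulled
into the linker (iterated to a fixpoint): functional groups such as linker
carbonyls are retained, not eliminated. Branches hanging off a linker by
single bonds remain side chains.

*Side chains and dot pairs.* The scaffold is the induced subgraph on ring
plus linker atoms. Cutting a single bond to a side chain restores one
implicit hydrogen at the cut point; cutting a double bond leaves a `pi_marker`
("dot pair") on the retained atom instead, preserving its sp² character
without adding phantom atoms — so descriptor counts of the scaffold are
unaffected. A triple-bond cut would increment the marker by two; no such
case occurs in the motivating set, and the serialized output makes the
marker visible so it can be audited. One consequence worth stating: a vinyl
or acetyl substituent attached to a ring by a *single* bond leaves no dot
pair — only the cut bond's own order counts — and an exocyclic C=O on a ring
atom is a side chain (the functional-group retention rule names linkers
only), so cyclohexanone's scaffold is a six-ring with one dot-pair carbon.

*Frameworks.* The framework is the scaffold with all atom and bond
attributes dropped. Canonical identification uses the BLISS canonical
labeling from igraph; the hash is the sorted edge list of the canonically
relabeled graph, so equality of hashes coincides with graph isomorphism.
The test suite checks this against an independently written brute-force
VF-style matcher on random graph libraries, and checks invariance under
vertex permutation and heteroatom mutation — the property that makes
framework grouping meaningful.

## Descriptors

* **HAC** — heavy atoms; **MW** — IUPAC average masses (3 decimals),
  implicit hydrogens included.
* **HBD** — hydrogens on N or O. **HBA** — N and O atoms, excluding
  positively charged atoms and pyrrole-type N (aromatic five-ring N-H),
  whose lone pair is part of the sextet. The reference table's donor and
  acceptor columns came from a descriptor package whose exact definitions
  are not recoverable, and a few rows are internally inconsistent (e.g. a
  quinoline fragment listed with ligand donors it cannot have); those cells
  are therefore not used as numeric targets, only the unambiguous ones
  (e.g. benzimidazole, HBD 1).
* **RotB** — non-ring single bonds between two non-terminal heavy atoms,
  excluding amide C–N bonds (the common convention; at fragment scale the
  ≤10 gate is insensitive to the convention's fine print). The selection
  gate is inclusive: exactly 10 rotatable bonds passes.

## Thermodynamics and normalization

Temperature is not part of the published protocol; T = 298.15 K is adopted
because the conversion constant it implies, c = ln 10 · R · T = 1.3642
kcal/mol, recovers all three published (BE, MW, BEI) triples to within
0.001. With c carried at full precision the recomputed BEI for the 3L58
fragment is 23.193 against a printed 23.20 — consistent with the original
analysis having used c rounded to 1.364 — so agreement is asserted at the
printed precision (±0.01), never tighter. The published LE of that same
fragment (0.377) is arithmetically irreproducible from its own BE and HAC
(−11.84/28 = 0.423); the fixture carries the printed value with an erratum
flag, reports exclude it from numeric checks, and recomputed values are what
the pipeline emits.

For plotting and ΔE series, all three score series are min–max scaled to
[0, 1], with binding energies scaled on their magnitude so "better binding"
is larger in every curve; the sign convention is a documented package
choice, since the original normalization formula is unstated. Constant
series are a degenerate-range error rather than silently zero.

Experimental IC50 entries may be ranges ("15-80"). Ranges are compared by
interval — a range beats a value only when its upper bound lies below it —
with midpoints deciding otherwise and the order flagged approximate. The LE
tie tolerance defaults to 0.005, the granularity at which the published
priority orders declare two fragments equivalent.

## The synthetic generator

`generate_library()` assembles molecules from 1–3 ring-system templates
(benzene, pyridine, a fused 6-6 bicycle, pyrimidinone, piperazine), joined
by methylene/ethylene/amide linkers and decorated with 0–4 small side chains
(methyl, hydroxyl, amino, methoxy, an acetamide chain) — the template
families echo the scaffold classes recurrent in small BACE-1 inhibitors
(arylpiperazines, pyrimidinones, benzimidazole-like fused aromatics,
isophthalamide-style amide linkers). Atom roles and template identities are
recorded at assembly, so dissection can be validated against construction
rather than against itself. Per-template additive energies sit in the −0.2
to −3.1 kcal/mol range, placing assembled ΔG values in the −2 to −12
kcal/mol band typical of docked fragments; `simulate_binding()` adds
Gaussian noise (default sd 0.25 kcal/mol, the scale at which rank orders
remain recoverable but not trivial) and clamps at zero from below. Seeds
are explicit arguments everywhere and the global RNG stream is restored on
exit.

What the generator deliberately does **not** emulate: 3D geometry and
docking-pose physics, stereochemistry, charged/tautomeric states,
non-additive (cooperative) binding, and molecules whose rings share atoms
with linkers. Passing the round-trip and recovery tests therefore shows the
dissection and scoring machinery is correct on molecules satisfying the
additivity and topology assumptions — not that those assumptions hold for
any particular real inhibitor series.

Validation problem sizes, chosen to give tight checks at interactive run
times: 100% atom-role recovery on 200 molecules × 3 seeds; OLS recovery of
all template energies within 3 standard errors at n = 500, noise 0.25;
hash invariance on 1000 random ≤12-node graphs plus all-pairs agreement
with the brute-force oracle on a 40-graph library.

## Known limitations

* Aromatic perception will not recognize aromatic rings written in Kekulé
  form as aromatic; donors/acceptors and the pyrrole-N exclusion then
  operate on the literal input form.
* The isostere table ships with the two classical swaps exercised by the
  motivating study (NH↔S in five-rings, CH↔N aromatic); it is
  config-extensible but makes no claim to completeness.
* `M CHG` property lines in SDF input are not interpreted (old-style atom
  block charges are); multi-record SDF files with query bond types (order 4)
  are rejected rather than guessed at.
* The published figure-level results that depend on the full 83-ligand
  structure set (the 13-framework census) are not reproducible from printed
  data, since the structures themselves are not published; the framework
  machinery is instead validated by the property tests above.
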