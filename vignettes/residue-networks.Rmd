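---
title: "Residue networks, interface motifs and differential centrality with prnkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue networks, interface motifs and differential centrality with prnkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prnkit)
```

## The model

A protein residue network (PRN) abstracts a protein or a protein complex
into a weighted undirected graph $G = (V, E)$: each residue of the PDB
file (or each FMO fragment) is a node, and an edge represents an
interaction between two residues.  prnkit builds two families of PRNs.

**Distance networks (D-PRN).**  The only criterion is a cutoff
$R_\mathrm{lim}$ on the centre-of-mass distance: $(i,j) \in E$ iff
$R_{ij} \le R_\mathrm{lim}$.  Centres of mass are mass-weighted over all
atoms present in the file, hydrogens included when the structure has them
(deposited X-ray structures usually do not; the choice matters only in
the second decimal of $R_{ij}$).  Edge weight is the distance itself.

**Energy networks (PIE-PRN).**  The mandatory criterion is a cutoff
$E_\mathrm{lim}$ on a pair interaction energy (PIE) term:
$(i,j) \in E$ iff $E_{ij} \le E_\mathrm{lim}$.  The comparison is signed —
a typical choice $E_\mathrm{lim} = -1$ kcal/mol keeps pairs bound by at
least 1 kcal/mol, and PIEDA components that can be positive (exchange
repulsion) are handled by the same rule.  An optional secondary
$R_\mathrm{lim}$ can additionally prune long-range pairs; it uses the
same centre-of-mass distance as the D-PRN (a closest-atom variant would
be an alternative, but keeping one distance definition makes the two
network families directly comparable).  Edge weight is
$w_{ij} = |E_{ij}|^{-1}$.

In both families the *importance* of an edge is $1/w_{ij}$.  This single
convention fixes the semantics everywhere downstream: weights behave like
distances (shortest paths, closeness, betweenness, efficiency), and
importances behave like connection strengths or conductances (Louvain
modularity, spectral clustering, current-flow betweenness).  Pairs with
an exactly zero accepted energy would have an undefined weight; they are
rejected with a warning (they can only occur with $E_\mathrm{lim} \ge 0$,
which is not a meaningful bound-pair criterion).

Sequence-adjacent residues are ordinary edge candidates by default
(`include_covalent = TRUE`): peptide-bonded neighbours interact strongly
and their edges are part of the published workflow this package follows.
Setting the flag to `FALSE` removes sequence neighbours from the
candidate set for users who want exclusively non-bonded topology.

## Energy sources

**Gamess FMO output.**  `parse_gamess_fmo()` locates the two-body pair
interaction (IFIE) table by a tolerant regular expression on the section
header, so small print-format drift between program versions does not
break parsing.  PIEDA columns (ES, EX, CT+mix, DI, optional solvation
screening) are captured when present.  Tables tagged as atomic units are
converted with 627.5095 kcal/mol per Hartree; tables already in kcal/mol
are taken verbatim.  Outputs of other FMO codes (Abinit-MP, PAICS) are
deliberately rejected rather than half-parsed.  FMO fragments of a
polypeptide are not exactly PDB residues — the backbone C,O atoms are
assigned to the neighbouring fragment — so the fragment map carries an
explicit offset note, and `map_fragments_to_residues()` offers positional
and number-based matching.

**Force-field energies.**  `compute_ff_pies()` evaluates residue pair
energies from an Amber prmtop on the structure exactly as given: no
cutoff, no periodicity, no minimisation.  Electrostatics use
$k_e q_a q_b / r_{ab}$ with $k_e = 332.0636$ kcal Å mol⁻¹ e⁻² and
charges de-scaled from Amber's internal units; van der Waals terms use
the topology's Lennard-Jones A/B coefficients.  Atom pairs separated by
one or two bonds are excluded and 1–4 pairs are scaled by 1/1.2
(electrostatics) and 1/2.0 (vdW), the Amber defaults (overridable via
`scee`/`scnb`).  Bond separation is computed from the bond list itself,
which is the robust topological definition and needs no dihedral
bookkeeping.

## Structure input choices

PDB parsing is delegated to bio3d; prnkit adds the policies the network
needs to be deterministic: for alternate locations only the
highest-occupancy conformer is kept (ties broken by altloc letter),
waters are dropped by default, HETATM ligands become nodes only on
request, the first model of a multi-model file is used, and residue
numbering is kept exactly as printed.  Numbering gaps are recorded per
chain because gaps are a natural place to cut a single-chain file into
"monomers" for interface analysis.  Element symbols fall back to the
first letter of the atom name when the element column is unreliable, with
a fixed IUPAC mass table behind `element_mass()`.

## Analyses

**Centralities.**  Degree is normalised by $n-1$; closeness and
betweenness are weighted by edge weight; on disconnected graphs closeness
follows the within-component convention scaled by $(s-1)/(n-1)$.
Current-flow betweenness is computed per connected component from the
Laplacian pseudoinverse with edge importance as conductance — physically,
strong interactions conduct more — and a node's score is its mean
throughput over all source–sink pairs of its component.  The total energy
centrality $C_k^{E\mathrm{tot}}$ sums $E_\mathrm{tot}$ over a node's
incident edges; strongly bound nodes are the most negative.

**Efficiency.**  The weighted global efficiency is
$E_\mathrm{glob} = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d(i,j)$ with
$1/d = 0$ for disconnected pairs.  The efficiency centrality is the
relative drop on node removal,
$C_k^\mathrm{eff} = (E_\mathrm{glob}(G) - E_\mathrm{glob}(G \setminus k)) / E_\mathrm{glob}(G)$;
it can be negative for peripheral nodes whose removal raises the mean.
The formula is stated here explicitly because the literature cites
several variants; this one is oracle-tested against remove-and-recompute
on small graphs.

**Folding degree.**  The per-residue folding degree is a spectral index
of backbone curvature.  For each chain the backbone atoms (N, CA, C in
residue order) define $M$ consecutive dihedral angles $\theta_i$; the
symmetric tridiagonal matrix with diagonal $\cos\theta_i$ and unit
off-diagonals couples neighbouring dihedrals, and its principal eigenpair
$(\lambda_1, v)$ yields per-angle contributions $\lambda_1 v_i^2$ summed
onto the residue owning the central bond.  Chain scores sum to
$\lambda_1$, the chain folding index.  The index depends only on
dihedrals, hence is invariant under rigid motion, and curled (helical)
backbones with small dihedrals outscore extended all-trans strands — the
two properties the suite asserts.  Readers should treat the absolute
numbers as an internal scale, not as comparable to other folding-degree
implementations.

**Partitions.**  Louvain communities maximise modularity with importance
as connection strength; the algorithm is stochastic, so prnkit seeds it
and reports the modularity of the returned partition (default resolution
1.0).  Spectral partitioning takes the $k$ lowest eigenvectors of the
importance-weighted normalised Laplacian, row-normalises and groups them
with seeded k-means (25 restarts); if fewer than $k$ distinct spectral
rows exist the distinct patterns themselves define the grouping.
Communities are indexed 1..m, following R conventions.

**Shortest paths** minimise total weight; among equally short paths the
lexicographically smallest node-label sequence is returned, so reports
are stable across igraph versions.

## Supramolecular analysis

`split_supersystem()` decomposes $G = G_A \cup G_B \cup G_\mathrm{PPI}$:
monomer subgraphs keep the intra-monomer edges, and the bipartite
interface graph $G_\mathrm{PPI}$ keeps only nodes with at least one
cross-monomer edge and only cross edges.  The edge sets of the three
parts partition $E(G)$ exactly (a property the suite checks), and
$G_{A\cup B}$ — all nodes, interface edges removed — is the NDA baseline.

**NDA.**  $\Delta C_k = C_k(G) - C_k(G_{A\cup B})$ isolates the effect of
the interface edges while comparing centralities on a common node set.
For the `etot` kind the identity
$\Delta C_k^{E\mathrm{tot}} = \sum_{\text{cross edges at } k} E_\mathrm{tot}$
holds exactly and is asserted without tolerance slack in spirit (1e-12,
i.e. floating-summation noise only).  The monomer baseline
($C_k$ on $G_A$/$G_B$) is retained behind a flag but warns: centralities
are generally not comparable across graphs of different size.

**SVD motifs.**  The interface matrix comes in two shapes: the
off-diagonal block (interface A-nodes × interface B-nodes) or the full
symmetric $N_\mathrm{PPI} \times N_\mathrm{PPI}$ adjacency of
$G_\mathrm{PPI}$.  A sign filter selects attractive, repulsive or all
interactions before decomposition — repulsive contacts are physically
informative but would otherwise be swamped.  Singular vectors have a sign
ambiguity; prnkit makes the largest-magnitude entry of each left vector
positive so motif membership reports are reproducible.  Dominant nodes of
a motif are those within a fraction `alpha` (default 0.5 — a generous
"within a factor of two of the leader" rule; the underlying literature
fixes no value) of the largest vector component, listed with their
strongest partners.

**SPIE and binding energies** read the *raw* pair table, not the
thresholded graph: the 3D-SPIE view exists precisely to show repulsive
and sub-threshold interactions that the $E \le E_\mathrm{lim}$ criterion
would hide, and fragment binding energies must conserve the total cross
energy, which a pruned edge set would not.  Binding energies are pair
sums only; many-body FMO corrections are out of scope.

## Synthetic fixtures and what they do (not) show

`make_toy_complex()` emulates the shape of the demonstration system the
methodology was published with — a short chain docked onto a longer one —
with two parallel chains of 3-atom pseudo-residues, a seeded subset of
aligned cross-chain pairs placed at 7 Å (contacts) versus ≥ 18 Å
(non-contacts), and a planted numbering gap.  The 8 Å cutoff stated in
the manifest separates the two populations with a margin much larger than
the ±0.15 Å jitter from mass-weighting, so the planted contact list *is*
the ground-truth edge set.  `make_toy_pie_table()` plants −5 kcal/mol
contact energies (the magnitude of a good hydrogen bond or salt bridge),
−2.5 kcal/mol peptide-neighbour energies, one mildly repulsive cross
pair, and a fixed PIEDA decomposition; Gaussian noise is optional and all
values are rounded to 1e-6 kcal/mol so the emitted pseudo-FMO text
round-trips exactly.  `make_toy_topology()` produces a small but complete
Amber prmtop (two LJ types, alternating charges, bonds that create 1-2,
1-3 and 1-4 pairs across residue boundaries).

These fixtures validate bookkeeping, criteria, identities and
decompositions.  They do not emulate real energetics (no conformational
strain, no solvation, no many-body effects), realistic secondary
structure, or the parser quirks of any particular Gamess build — passing
tests certify the graph machinery, not chemical accuracy on real systems.

## Numerical choices and limitations

* Energies are kcal/mol, distances Å, reports `%.6f`-formatted;
  Hartree-to-kcal conversion uses 627.5095.
* All randomised steps (fixtures, Louvain, k-means) take explicit seeds
  and restore the caller's RNG state.
* Current-flow betweenness is $O(n^2 m)$ per component and is the
  slowest centrality; for networks beyond a few hundred residues expect
  it to dominate runtime.
* The test suite and the acceptance script run on deliberately small
  problems (complexes of ≤ 24 residues, matrices ≤ 8×8, 50-atom
  topologies) so that exhaustive brute-force oracles — path enumeration,
  all set partitions, double loops over atom pairs — remain feasible
  companions to every analytical claim.
* The prmtop reader consumes the standard sections only (no CMAP, no
  polarisabilities); 10-12 hydrogen-bond terms are treated as absent.
* mmCIF input, structure repair, hydrogen addition, molecular-dynamics
  trajectories and any GUI/rendering concerns are out of scope.

## A complete run

```{r example, eval = FALSE}
pdb <- system.file("extdata", "toy_complex.pdb", package = "prnkit")
fmo <- system.file("extdata", "toy_complex_fmo.log", package = "prnkit")
out <- run_analysis(list(
  pdb = pdb, fmo = fmo,
  criteria = list(e_lim = -1),
  monomer_a = "A", monomer_b = "B",
  analyses = c("edges", "centrality", "partition", "nda", "svd",
               "spie", "binding", "export"),
  seed = 1, out_dir = tempfile("prn_")))
basename(out)
```

Every report is a TSV keyed by the canonical node label
`chain:number[:icode]:name`, and `run.log` records the criteria, counts
and package version of the run.
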