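# prnkit — protein residue networks from structure and interaction energies

prnkit is an R toolkit for **protein residue network (PRN)** analysis,
aimed at structural biologists and computational chemists who want to study
protein–protein (or protein–ligand) interfaces at residue resolution.  A
PRN is a weighted undirected graph whose nodes are residues (or FMO
fragments) and whose edges are inter-residue interactions.  Two network
families are supported:

* **D-PRN** — an edge joins residues *i, j* when their centre-of-mass
  distance satisfies *R<sub>ij</sub> ≤ R<sub>lim</sub>*; the edge weight is
  *w<sub>ij</sub> = R<sub>ij</sub>*.
* **PIE-PRN** — an edge joins residues when their pair interaction energy
  satisfies *E<sub>ij</sub> ≤ E<sub>lim</sub>* (signed comparison, e.g.
  −1 kcal/mol); the weight is *w<sub>ij</sub> = |E<sub>ij</sub>|⁻¹*, so
  strongly bound pairs are "close".  Energies come either from a Gamess
  FMO calculation (IFIE tables, optionally PIEDA-decomposed into
  electrostatic/exchange/charge-transfer/dispersion terms) or from
  force-field parameters in an Amber topology evaluated on the static
  structure.  The edge importance is always the inverse of the weight.

On top of the graphs prnkit provides degree, closeness, betweenness and
current-flow betweenness centralities, the **total energy centrality**
*C<sub>k</sub><sup>Etot</sup> = Σ<sub>(k,j)∈E</sub> E<sub>tot</sub>(k,j)*,
weighted global/local efficiency and the **efficiency centrality**
*(E<sub>glob</sub>(G) − E<sub>glob</sub>(G∖k)) / E<sub>glob</sub>(G)*,
residue folding degree, shortest paths, and Louvain / spectral partitions.

For a complex *G* of monomers A and B the graph is split as
*G = G<sub>A</sub> ∪ G<sub>B</sub> ∪ G<sub>PPI</sub>*, where the bipartite
interface graph *G<sub>PPI</sub>* holds only cross-monomer edges.  This
enables:

* **Network differential analysis (NDA)** — *ΔC<sub>k</sub> =
  C<sub>k</sub>(G) − C<sub>k</sub>(G<sub>A∪B</sub>)*, the centrality change
  attributable to interface edges (*G<sub>A∪B</sub>* keeps all nodes and
  drops only interface edges, so scores are size-consistent);
* **SVD motif analysis** — the interface energy matrix is decomposed as
  *M = U Σ V\**; each rank-1 term *σ<sub>i</sub> u<sub>i</sub> ⊗ v<sub>i</sub>\**
  is an interaction motif, and *f<sup>(r)</sup> = Σ<sub>i≤r</sub> σ<sub>i</sub> /
  Σ<sub>i≤k</sub> σ<sub>i</sub>* measures how much of the interface the
  leading motifs capture;
* **3D-SPIE tables** — all raw cross-monomer pair energies with
  attractive/repulsive labels;
* **per-fragment binding energies** — symmetric or asymmetric division of
  the total inter-monomer interaction energy.

Graphs export to GEXF 1.2 and GraphML with all attributes.

## Worked example

A small synthetic complex ships with the package: chain A (6 residues)
docked onto chain B (12 residues, with a numbering gap after residue 2),
plus a matching pseudo-FMO pair-energy table.

```r
library(prnkit)

pdb <- system.file("extdata", "toy_complex.pdb", package = "prnkit")
fmo <- system.file("extdata", "toy_complex_fmo.log", package = "prnkit")

s   <- parse_pdb(pdb)
#> prn_structure: 18 residues, 54 atoms, chains {A,B}
#>   numbering gaps: B after 2

pie <- parse_gamess_fmo(fmo)$pie
g   <- build_pieprn(pie, build_criteria(e_lim = -1), structure = s)
memb  <- setNames(ifelse(s$residues$chain == "A", "A", "B"), s$residues$label)
split <- split_supersystem(g, memb)
#> prn_split: |V(G)|=18 |E(G)|=19; N_A=6 N_B=12; interface: 6 nodes, 3 edges

round(sort(nda(split, "etot")$delta)[1:4], 3)
#> B:6:ALA A:5:ALA A:6:ALA B:7:ALA
#>  -5.787  -5.787  -5.243  -5.243
```

The most negative ΔC<sup>Etot</sup> values single out the residues whose
binding is most strengthened by the interface — here the planted contact
pairs A5–B6 and A6–B7 (ΔC equals the summed cross-edge energy of each
node, in kcal/mol).  The interface motifs tell the same story:

```r
sv <- svd_motifs(ppi_matrix(split, sign_filter = "attractive"))
round(sv$f_series, 3)
#> [1] 0.361 0.687 1.000
dominant_motif_nodes(sv, ppi_matrix(split, sign_filter = "attractive"), 1, side = "A")
#>      node component        partners
#> 1 A:5:ALA         1 B:6:ALA(-5.787)
```

The first motif is carried entirely by the strongest contact (A5 with
partner B6 at −5.787 kcal/mol); two motifs capture 68.7% of the singular
value sum.  Community structure and efficiency summarise the topology:

```r
louvain_communities(g, seed = 1)
#> prn_partition (louvain): 4 communities over 18 nodes, modularity 0.5684
global_efficiency(g)
#> [1] 0.9307
binding_energies(pie, memb, mode = "symmetric")
#> prn_binding (symmetric): total cross energy -15.910 kcal/mol over 18 fragments
```

The same pipeline runs from the shell via the bundled script:

```sh
Rscript inst/exec/prn-run --pdb toy_complex.pdb --fmo toy_complex_fmo.log \
    --elim -1 --monomer-a A --monomer-b B \
    --analyses edges,centrality,partition,nda,svd,spie,binding,export \
    --seed 1 --out results/
```

All reports are tab-separated text with fixed `%.6f` formatting; runs are
byte-for-byte reproducible given the seed.

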