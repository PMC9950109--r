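---
title: "Identifying versatile fragments from protein-fragment complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying versatile fragments from protein-fragment complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragverse)
```

## The question the package answers

A fragment that has been crystallized with several proteins can bind them
all in essentially the same way, or it can rearrange its interactions to
fit each environment. The second kind — *versatile* fragments — are
interesting for fragment-based drug discovery because their adaptability
predicts screening hits across unrelated targets. fragverse identifies
them from a collection of protein–fragment complexes by requiring, for the
same chemical component (HET code), at least two distinct **binding modes**
and at least two dissimilar **binding cavities**, then characterizes the
survivors chemically.

## Binding modes as interaction graphs

Four interaction classes are detected from geometry alone:

| interaction | rule (defaults) |
|---|---|
| hydrogen bond | donor–acceptor heavy atoms ≤ 3.5 Å, D–H···A angle ≥ 120° |
| ionic | opposite formal charges ≤ 4.0 Å |
| aromatic stacking | ring centroids ≤ 5.0 Å, interplanar angle ≤ 30° or 60–90° |
| hydrophobic | apolar C/S atoms ≤ 4.5 Å |

The distance and angle thresholds are not part of the published method
description (the original detection is delegated to a closed tool); the
values above are the customary ones for geometric interaction
fingerprinting and every one of them is a `geom_rules()` argument. Three
conventions close genuinely open choices: an ionic pair suppresses a
hydrogen bond between the same two atoms; aromatic-ring carbons engage
through stacking rather than hydrophobic contacts (otherwise every stacked
ring would also spray hydrophobic pseudo-atoms); and adjacent hydrophobic
ligand atoms contacting one residue collapse to their closest pair, which
keeps large greasy surfaces from flooding the graph with near-duplicate
nodes.

Each interaction places a pseudo-atom labeled with its type on the ligand
interacting atom (the ring centroid for stacking). A hydrogen bond places a
second pseudo-atom at the exact midpoint between donor and acceptor so the
bond's direction is part of the fingerprint; donor and acceptor carry
distinct labels by default. Edges connect all node pairs and carry
Euclidean lengths, so the graph is invariant under rigid motion of the
complex — binding modes are compared, not poses.

Two graphs are compared with a subgraph matching kernel: every injective
label-preserving mapping of up to three nodes contributes the product of
edge kernels $k_e(d_1, d_2) = \max(0, 1 - |d_1 - d_2| / 1\,\mathrm{Å})$
over mapped edge pairs; each mapping is counted once as a set of node
pairs. The raw kernel is cosine-normalized, giving 1 for identical graphs
and 0 for graphs without a shared label. Modes are then DBSCAN clusters at
eps = 0.23 on 1 − similarity with min_samples = 2. Two decisions here are
the package's own: an isolated graph counts as its own binding mode (a
fragment seen twice with unrelated graphs must yield two modes for the
funnel to make sense), and the published shape-overlap merge correction —
which relied on a proprietary scoring function — is replaced by its stated
intent: clusters merge when every graph of one embeds, label-preserving
and with all edge lengths within 0.5 Å, into some graph of the other, with
transitive closure. The merge never increases the mode count and is
idempotent.

## Binding cavities as labeled point clouds

The pocket is described from the fragment outward: lattice points
(spacing 1.5 Å) are kept if they lie within 4 Å of a fragment heavy atom,
at least 2 Å from every protein heavy atom, and buried (at least 7 of 14
lattice ray directions hit a protein atom within 8 Å, ray half-width
1.5 Å). Each point takes the pharmacophoric type of the nearest protein
heavy atom within 4 Å — charged beats hydrogen-bonding beats aromatic beats
hydrophobic — or DUMMY. The 4 Å fragment distance is the published value;
spacing, clash distance and the buriedness test are this package's
reconstruction of the cavity-delineation step and are `pipeline_config()`
parameters.

Cloud comparison is rigid registration: per-point neighbor-label histograms
propose same-label correspondences, RANSAC over 3-point samples finds a
transform, label-constrained ICP refines it, and the score is the fraction
of the smaller cloud's points with a same-label counterpart within 1.5 Å.
The comparison runs in both directions and keeps the better score, so it is
symmetric by construction. Identical clouds score 1; clouds without a
common label score 0.

The published procedure uses 0.47 both as "scores below this mean
dissimilar sites" and as a clustering eps. These readings conflict: an eps
of 0.47 on 1 − score joins clouds with score > 0.53. The package follows
the stated meaning of the threshold — observations cluster iff their score
is **at least 0.47** (eps = 0.53 on the distance) — and offers
`literal_eps = TRUE` for the strict reading. On data with clearly similar
(score ≈ 0.9) and clearly dissimilar (score ≈ 0.3) pairs the two readings
agree.

## Chemistry characterization

The unwanted-ligand categories (monosaccharide, prosthetic group,
crystallization additive, polyatomic ion, polyhalogenated, linear
aliphatic) are detected by a packaged HET-code blocklist reconstructed from
the usual screening-database exclusion lists plus SMARTS/graph heuristics,
because the original curation lists are external. The PAINS catalog shipped
in `inst/extdata/pains_smarts.tsv` is a curated subset of the public
A/B/C interference families (quinones, catechols, rhodanines, hydrazones,
azo compounds, ...) written in SMARTS the toolkit parses; it is smaller
than the 652-rule commercial filter used originally, so absolute PAINS
counts will differ — the operation and its reporting are the same, and the
catalog is a plain text file users can extend.

Descriptors (MW, logP, TPSA, H-bond donors/acceptors, rotatable bonds,
charges) use OpenBabel's standard atomic-contribution schemes; exact parity
with commercial descriptor software is not expected, and logP in
particular can differ by a few tenths. The plane of best fit is the mean
absolute distance of heavy atoms to their least-squares (SVD) plane, 0 for
flat molecules; by default it is computed on the crystallographic
conformer. Bemis–Murcko scaffolds prune terminal atoms iteratively,
keeping exocyclic double-bonded atoms. Substructure contribution converts
the query to a SMARTS pattern (chirality marks kept or stripped) and, on a
match, reports bonds(query)/bonds(target), 1 meaning an exact match.

Sequence relatedness uses Smith–Waterman local alignment (BLOSUM62, gap
opening 10, extension 0.5) via Biostrings; a gap of length L costs
open + L·extend, and the test suite pins the scores to an independent
dynamic-programming oracle. Identity is identical pairs over aligned
columns; alignments shorter than 100 columns are ignored (distance forced
to 1); clustering at eps 0.10 groups the same protein or close homologs
(≥ 90% identity), at 0.75 homologs at ≥ 25%. When no chain holds more than
half of a binding site's residues, the plurality chain is used and the
result flagged.

## What the synthetic generator emulates — and what it does not

`synth_complex()` builds minimal complexes: fragment anchor atoms with
explicit polar hydrogens and single-atom probe residues placed so the
detector returns exactly the requested interactions (validated closed-loop
at construction). `synth_mode_family()` plants K modes using five
interaction templates with pairwise-distinct label multisets; contact
distances sit at least 0.5–0.7 Å inside the detection cutoffs so that the
default coordinate jitter (σ = 0.05 Å, up to 0.1 Å in the recovery suites)
cannot flip an interaction on or off. `synth_cavity_set()` plants M
environments, each 80% one primary label and 20% DUMMY, observed as rigid
copies with optional label noise; cross-environment scores are bounded by
the DUMMY fraction (0.2), well under the 0.47 decision value.
`synth_corpus()` writes complete PDB entries — probes plus a surrounding
cage of non-interacting polar atoms (≥ 5 Å from every fragment atom,
outside all interaction cutoffs) whose element pattern defines the cavity
environment — together with a SMILES manifest and a ground-truth table,
deterministically under a fixed seed. Corpus templates avoid formal
charges, which plain coordinate files do not preserve.

Passing the recovery suites therefore shows that each stage inverts its
generator under the stated margins: correct interaction typing, correct
mode counts for K ∈ 1..5, correct cavity counts for M ∈ 1..5, correct
funnel decisions for every decoy class. It does **not** show performance on
real crystal structures, where protonation is ambiguous, densities are
imperfect, pockets are ragged, and binding modes form continua rather than
well-separated clusters. The two crystallographic worked examples (PQ0,
H3M) cover that gap when the corresponding PDB entries are supplied; the
test enforcing them is part of the suite and requires those files locally.

## Numerical choices and degenerate inputs

Problem sizes in the shipped suites — graphs of ≤ 5 nodes against the
enumeration oracle (500 pairs), 100-run recovery grids, corpora of 8
fragments over 29 entries — were chosen so each property is exercised
across its parameter range while the whole suite stays comfortably
reproducible on a laptop. Other numerical decisions:

* Kernel ties and conventions are fixed by a worked example in the test
  suite (two 2-node graphs, edges 2.0 vs 2.5 Å, similarity 5/6), so the
  implementation and the independent oracle agree by construction, not by
  tuning.
* RANSAC uses at most 300 seeded iterations with early exit on an inlier
  fraction ≥ 0.95 and a plateau exit after 50 fruitless iterations; ICP
  runs at most 8 rounds and keeps only score-improving refinements.
  Registration is deterministic given the seed threaded from
  `pipeline_config()$random_seed`.
* Clouds with fewer than 3 points fall back to label-bag overlap and are
  flagged low-confidence; empty sites and empty clouds quarantine the
  entry rather than erroring the run.
* RSCC classes are closed at both boundaries on the PARTIAL side
  (0.8 ≤ RSCC ≤ 0.9), exactly as published; a ligand absent from a
  validation file yields NA, never 0, and site means shrink their
  denominator over residues present in the file.
* Hydrogen placement is valence-based with standard bond lengths (N–H
  1.01, O–H 0.96, S–H 1.34 Å); carbonyl-like and negatively charged
  oxygens receive none, aromatic ring nitrogens default to the
  unprotonated state. Protonation-sensitive results (a fragment whose
  modes differ only by protonation state) need a per-entry override;
  this is a known limitation.
* Ligands without hydrogens downgrade hydrogen-bond detection to
  heavy-atom distances with a warning, only when donor-capable atoms
  exist.

## Known limitations

Backbone superposition takes its residue correspondence from the sequence
alignment, not from a structural aligner, so RMSD values for remote
homologs are indicative only. The PAINS subset undercounts relative to the
commercial 652-rule filter. Descriptor values are toolkit-specific.
Water-mediated and weak hydrogen bonds, halogen bonds, cation–π and metal
coordination are outside the four detected interaction classes. Nucleic
acid sites are out of scope.
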