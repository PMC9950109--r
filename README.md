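# fragverse

Mining protein–fragment crystal structures for **versatile fragments** —
low-molecular-weight compounds (MW < 300 Da, 2–18 heavy atoms) observed with
two or more distinct binding modes *and* in two or more dissimilar binding
cavities. Such fragments adapt their interaction pattern to unrelated protein
environments, which makes them attractive starting points for
fragment-based drug discovery: they are more likely to give hits across
targets than fragments that always bind one way.

The package is aimed at structural bioinformaticians and computational
chemists who want to run the selection on their own structure collections,
or to validate each stage of the method on synthetic data with planted
ground truth.

## Method

Candidate fragments pass a five-step funnel:

1. **Fragment definition** — remove molecules that are not fragments:
   MW ≥ 300 Da, heavy atoms outside [2, 18], monosaccharides,
   organometallics, prosthetic groups, crystallization additives, simple
   polyatomic ions, small polyhalogenated compounds, linear aliphatics.
2. **Occurrence** — keep fragments present in more than one structure entry.
3. **Binding modes** — each complex is encoded as an *interaction graph*:
   hydrogen bonds, ionic bonds, aromatic stacking and hydrophobic contacts
   detected by geometric rules each place a typed pseudo-atom on the ligand
   interacting atom (hydrogen bonds add a second pseudo-atom halfway to the
   protein partner); the complete graph over these nodes carries Euclidean
   edge lengths. Graphs of one fragment are compared with a subgraph
   matching kernel

   k(G₁, G₂) = Σ over injective label-preserving mappings of ≤ 3 nodes of
   Π over mapped edge pairs of max(0, 1 − |d₁ − d₂| / 1 Å),

   cosine-normalized to [0, 1]. Binding modes are DBSCAN clusters
   (eps = 0.23 on 1 − similarity, min_samples = 2; isolated graphs count as
   their own mode), followed by a correction that merges clusters whose
   graphs embed into the graphs of another cluster. Fragments with ≥ 2 modes
   continue.
4. **Binding cavities** — the pocket around each bound fragment is a cloud
   of lattice points within 4 Å of the fragment's heavy atoms, clash-free
   and buried, each labeled with the pharmacophoric type of the nearest
   protein atom. Clouds are compared by label-aware rigid registration
   (descriptor matching, RANSAC, label-constrained ICP, both directions,
   best score kept); the score is the same-label inlier fraction of the
   smaller cloud. Observations cluster together iff their score is at least
   0.47; fragments bound in ≥ 2 dissimilar cavities continue.
5. **PAINS** — fragments matching pan-assay-interference SMARTS motifs are
   removed.

Downstream characterization: molecular descriptors, rule-of-three
violations, plane of best fit (mean distance of heavy atoms to their
least-squares plane), Bemis–Murcko scaffolds, substructure contribution
(bond-count ratio of a fragment embedded in a superstructure),
real-space-correlation (RSCC) quality classes, Smith–Waterman sequence
relatedness of the binding proteins (BLOSUM62, gaps 10/0.5, identity
clustering at ≥ 90% and ≥ 25%), and symmetry-aware conformer RMSD.

## Worked example

Generate a synthetic corpus with three planted versatile fragments and five
decoys (one per rejection step), then run the pipeline:

```r
library(fragverse)
dir <- tempfile("corpus")
synth_corpus(synthetic_spec(n_versatile = 3, K = 2, M = 2, n_obs = 4,
                            seed = 11), dir)
report <- run_pipeline(dir)
report
#> <pipeline_report>
#>   fragments in: 8
#>   after step 1 (fragment definition): 7
#>   after step 2 (multi-entry): 6
#>   after step 3 (>=2 binding modes): 5
#>   after step 4 (>=2 cavities): 4
#>   after step 5 (PAINS-free): 3
#>   versatile: V01, V02, V03
```

Each step removes exactly one decoy: the sulfate ion (not a fragment), the
single-entry fragment, the single-mode fragment, the single-cavity fragment,
and the catechol (PAINS). The three planted versatile fragments survive,
each with `n_binding_modes = 2` and `n_cavities = 2` — the planted values.
`export_deposit(report, "out/")` writes the result tables
(versatile fragments with SMILES, mode and cavity counts; post-step-2
fragments; entry metadata; RSCC scores; substructure-search results) and
per-instance MOL2 files.

Individual stages are exposed directly: `read_structure()`,
`ensure_hydrogens()`, `extract_site()`, `detect_interactions()`,
`build_interaction_graph()`, `smk_similarity()`, `count_binding_modes()`,
`generate_cavity_cloud()`, `cavity_similarity()`, `count_cavities()`,
`classify_ligand()`, `pains_flags()`, `compute_descriptors()`,
`murcko_scaffold()`, `substructure_contribution()`, `smith_waterman()`,
`cluster_by_identity()`, `symmetry_rmsd()`. A thin command-line wrapper
lives in `inst/scripts/fragverse`.

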