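# kinnet

Protein kinase inhibitors do more than block an ATP pocket: binding
reorganises the residue interaction network of the whole kinase domain, and
clinically important resistance mutations cluster at residues that mediate
that reorganisation. **kinnet** is an R package for quantifying this
network view of inhibitor binding. It is written for structural
bioinformaticians and computational chemists who want the full chain of
analyses — ensemble dynamics, contacts and surface area, weighted residue
networks, coevolution, and binding energetics — as composable, tested,
tibble-first functions rather than a web service.

## What it computes

* **Residue interaction networks.** Side-chain heavy-atom contacts at
  4.5 Å are normalized into interaction strengths
  `I_ij = n_ij / sqrt(N_i N_j) × 100` (%); pairs with `I_ij > 3%` become
  edges, weighted by residue cross-correlations as `w_ij = −log|C_ij|`. A
  bound ligand enters as an extra node bridging its contact residues.
* **Betweenness centrality** via Floyd–Warshall with co-optimal path
  counting, normalized per connected component by `(N−1)(N−2)/2`, and
  apo→holo centrality differences (`delta_centrality()`) that expose the
  ligand's network-bridging effect.
* **Ensemble dynamics**: Kabsch superposition, B-factors
  `B = (8π²/3)⟨Δr²⟩`, residue cross-correlation matrices, essential
  dynamics (PCA), and anisotropic-network-model normal modes.
* **Contacts and surfaces**: LPC-style 8-class contact classification,
  ensemble-averaged ligand contact profiles, Shrake–Rupley SASA and
  relative solvent accessibility.
* **Coevolution**: mutual information between alignment columns (nats),
  permutation z-scores (the conventional 6.5 edge threshold lives on this
  scale), Kullback–Leibler conservation, cumulative MI (cMI) and
  structure-local proximity MI (pMI, 5 Å), with circular-network export.
* **Binding energetics**: MM-GBSA combination
  `ΔG_bind = ⟨ΔG_MM⟩ + ⟨ΔG_solv⟩ − ⟨TΔS⟩` over a minimal LJ/Coulomb/GB/SA
  backend (`σ_np = 0.0072 kcal mol⁻¹ Å⁻²`), and computational alanine
  scanning (Cβ truncation on wild-type frames, side-chain-only
  minimization, entropy omitted).
* **Synthetic study systems**: seed-deterministic generators of toy
  structures, mode-driven ensembles, alignments with planted conservation
  and coevolution (a fully coupled pair has MI exactly ln 2), and
  apo/holo complexes whose ligand bridges two weakly connected lobes.

Everything joins on one key — `"chain:seq_id"`, with author numbering
preserved verbatim from the source PDB — so profiles from different stages
merge with ordinary dplyr verbs.

## Worked example

A 20-residue two-lobe complex whose ligand bridges pocket residues 3 and
18 across the inter-lobe cleft:

```r
library(kinnet)

cx  <- gen_complex(complex_spec(20, pocket_residues = c(3, 18),
                                ligand_atoms = 6, seed = 1))
ens <- gen_ensemble(cx$holo, 100, noise_sd = 0.2, seed = 2)

corr   <- cross_correlation(superpose(ens))
g_apo  <- build_graph(cx$apo,  correlation = corr, weighting = "correlation")
g_holo <- build_graph(cx$holo, correlation = corr, weighting = "correlation",
                      ligand_contacts = ensemble_ligand_contacts(ens))
g_holo
#> # kin_graph: 21 nodes, 39 edges (I_min 3.0%, correlation weighting)

dc <- delta_centrality(betweenness_centrality(g_apo),
                       betweenness_centrality(g_holo))
dplyr::arrange(dc, dplyr::desc(delta))
#> # A tibble: 20 × 5
#>   key   res_type betweenness_apo betweenness_holo  delta
#>   <chr> <chr>              <dbl>            <dbl>  <dbl>
#> 1 A:3   VAL               0.140             0.363 0.223
#> 2 A:18  THR               0.140             0.363 0.223
#> 3 A:5   PHE               0.0234            0.1   0.0766
#> # …
```

The two pocket residues gain the most betweenness on binding: the ligand
has opened a new shortest-path channel between the lobes that runs through
them — the network-bridging signature. The same residues dominate the
energetic map:

```r
alanine_scan(ens, residues = c("A:3", "A:18"), subsample = 4)
#> # A tibble: 2 × 8
#>   key   res_type    ddG ddG_vdw ddG_np ...
#> 1 A:3   VAL       0.347   0.192  0.155
#> 2 A:18  THR      -0.194  -0.394  0.200
```

`ddG` is the change in binding free energy (kcal/mol) on truncating the
side chain to alanine, decomposed term by term; positive values mean the
wild-type side chain favours binding. Every result type has `tidy()`,
`glance()` and `autoplot()` methods, and `run_pipeline()` drives all
stages from a YAML config (`demo_config()` writes a ready-to-run synthetic
demonstration).

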