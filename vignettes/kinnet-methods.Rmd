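---
title: "Methods: residue interaction networks, coevolution and binding energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue interaction networks, coevolution and binding energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinnet)
```

# Scope

kinnet links inhibitor binding to the global organisation of a protein
kinase through four connected analyses: ensemble dynamics statistics,
side-chain contact and surface-accessibility profiles, a weighted residue
interaction network with betweenness centrality, and sequence-based
coevolution scores mapped onto the structure, plus an MM-GBSA binding
free-energy layer with computational alanine scanning. Everything runs on
synthetic, seed-controlled systems, so the statistical machinery is
testable against closed forms and planted ground truth without any
molecular-dynamics engine or external download.

# The residue interaction network

Residues are nodes; two residues are joined when the normalized strength of
their side-chain contact exceeds a threshold. For residues $i$ and $j$ with
$n_{ij}$ side-chain heavy-atom pairs within 4.5 Å,

$$I_{ij} = \frac{n_{ij}}{\sqrt{N_i N_j}} \times 100,$$

where $N_i$ is a residue-type normalization factor: the largest number of
heavy-atom contact pairs (main chain and side chain) that a residue of that
type makes to all of its surroundings anywhere in the input set. An edge is
admitted when $I_{ij} > I_{\min}$, with $I_{\min} = 3\%$ by default. Two
choices deserve comment:

* **Functional form.** The geometric-mean normalization
  $n_{ij}/\sqrt{N_iN_j}$ is the classical side-chain interaction-strength
  scheme; a plain product $n_{ij}/(N_iN_j)$ is available via
  `form = "product"` for sensitivity analysis, but it compresses the scale
  so strongly that the conventional 3% threshold would admit nothing.
* **Normalization data.** Published per-type factors are not shipped;
  `normalization_factors()` derives them from the input structures
  (dataset mode, a documented reconstruction) or loads a user table, which
  takes precedence when both are given.

Residue pairs adjacent in sequence are covalent neighbours rather than
interactions and are excluded by default (`exclude_adjacent = FALSE`
restores them). Glycine, which has no side chain, contributes its CA atom
so that it can form edges at all.

Under correlation weighting each edge carries
$w_{ij} = -\log |C_{ij}|$, where $C_{ij}$ is the cross-correlation of
residue fluctuations from an ensemble, so strongly coupled residues are
close in network distance. $|C_{ij}|$ is clamped to
$[10^{-6}, 1 - 10^{-6}]$ before the logarithm: an uncorrelated pair would
otherwise produce an infinite edge and a perfectly correlated pair a
zero-length one, and finite shortest-path arithmetic needs neither.

A bound ligand becomes a single extra node with an edge to every residue
whose mean ensemble contact count is at least 1. The edge weight is the
median protein edge weight: the ligand's "distance" through the network is
then typical of a protein contact rather than an artefact of any
correlation entry, which an ensemble cannot supply for a rigid ligand
model. Atom-level ligand nodes were considered and rejected: with no
defensible weighting scheme for atom-atom edges the choice would dominate
the very centrality changes the analysis is about.

## Shortest paths and betweenness

All-pairs distances use Floyd–Warshall; co-optimal path multiplicities are
then counted per source in order of increasing distance. Paths within a
relative $10^{-9}$ of the minimum count as co-optimal — floating-point edge
weights make exact ties meaningless. Normalized betweenness of node $i$
sums, over unordered pairs $j<k$ in $i$'s connected component, the fraction
of co-optimal paths through $i$, divided by $(N-1)(N-2)/2$ with $N$ the
component size; components smaller than 3 score zero. The suite checks this
against exhaustive simple-path enumeration on hundreds of random weighted
graphs, and against igraph distances; both weighted and topological
variants are exposed because either convention is defensible for the
published centrality profiles.

The ligand-bridging effect is quantified as
$\Delta C_b = C_b^{\mathrm{holo}} - C_b^{\mathrm{apo}}$ on shared residue
keys, ligand node excluded.

# Ensemble dynamics

Frames are superposed by Kabsch least-squares rotation (proper rotation
enforced by the determinant correction, verified against a brute-force
rotation search on a chiral toy). B-factors follow
$B_i = \tfrac{8\pi^2}{3}\langle \Delta r_i^2 \rangle$ averaged over the
selected atoms of each residue. Cross-correlations
$C_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
\sqrt{\langle \Delta r_i^2\rangle\langle \Delta r_j^2\rangle}$ use CA atoms
by default (the convention is exposed as a flag; the backbone-average
variant is also available). Residues with zero variance cannot be
normalized; their entries are set to 0 with a warning.

PCA diagonalises the positional covariance; following the standard
essential-dynamics convention the "lowest-frequency" modes are the
largest-variance components, and the mobility profile is the
root-mean-square displacement magnitude of each residue over the three
leading modes. The anisotropic network model builds the conventional
CA-contact Hessian (cutoff 15 Å, uniform spring constant 1 — the usual
defaults in the absence of a stated parameterisation); a connected
structure must show exactly six near-zero eigenvalues, and a disconnected
contact graph is an error naming the components rather than a silent
seventh zero mode.

# Contacts and surface area

Contacts are counted between side-chain heavy atoms at an inclusive 4.5 Å
cutoff (a pair exactly at the cutoff counts). Each contacting pair is
tallied under one of eight LPC-style atom classes (hydrophilic,
hydrophobic, aromatic, acceptor, donor, neutral, neutral-donor,
neutral-acceptor), taken from a shipped, editable table keyed by residue
type and atom name. The table reconstructs the published LPC
classification scheme rather than inventing classes per run; users with
their own conventions can supply a replacement file. Ligand contact
profiles are ensemble means of per-frame counts, classified by the protein
atom of each pair so tallies partition the total exactly.

Solvent-accessible surface area uses Shrake–Rupley with a deterministic
golden-spiral quadrature, 960 points per atom by default (isolated-sphere
error well under 1%; doubling the points moves a 10-residue toy's total by
less than 0.5%). Radii come from a Bondi-style element table; an unknown
element is an error, never a silent default. Relative solvent
accessibility divides the observed residue area by a shipped
theoretical-maximum reference table (tripeptide-based values), overridable
by file; values slightly above 1 are legitimate for highly exposed
residues.

# Coevolution scores

Mutual information between alignment columns uses the plug-in estimator in
nats, with optional sequence weights ($1/\text{cluster size}$ under
single-linkage clustering at 62% identity). Sequences gapped at either
column are dropped from that pair's joint counts by default; a
gap-as-21st-symbol policy is available. The per-column conservation score
is the standard Kullback–Leibler divergence
$\sum_a P(a)\ln\!\big(P(a)/Q(a)\big)$ against a shipped database-wide
background (renormalised to sum to one; a uniform background serves the
closed-form tests). An unweighted variant that simply sums
$\ln\!\big(P(a)/Q(a)\big)$ over observed residues is provided as
`form = "printed"` for comparability, but the weighted form is the default
because only it is a proper divergence (non-negative, zero exactly at the
background).

The conventional coevolution-network threshold of 6.5 cannot be a raw
plug-in MI value: MI over a 20-letter alphabet is bounded by
$\ln 20 \approx 3.0$. It is therefore applied on a permutation z-score
scale: columns are shuffled independently (preserving each column's
composition and gap mask), the MI matrix recomputed, and
$z = (MI - \mu_0)/\sigma_0$ taken against the null moments. The null is
pooled across pairs by default, which is stable at modest permutation
counts and works well when columns share comparable alphabets; per-pair
moments (`pooled = FALSE`) are preferable when planted or highly conserved
columns make the pair ensemble heterogeneous, and both are tested. The
cumulative score $cMI_x$ sums MI over partners whose score clears the
threshold; the proximity score $pMI_x$ averages $cMI$ over residues within
5 Å minimal heavy-atom distance of $x$ on the mapped structure (the
summation in the printed definition is garbled; the implementation follows
the accompanying text). Residues with no neighbour are reported as missing
rather than silently zeroed.

Column-to-residue mapping walks the reference row's non-gap columns in
order; below 90% identity to the structure sequence the mapping aborts,
and individual mismatches are reported in the output rather than dropped.

# Binding energetics

The MM-GBSA combination
$\Delta G_{\mathrm{bind}} = \langle\Delta G_{MM}\rangle +
\langle\Delta G_{\mathrm{solv}}\rangle - \langle T\Delta S\rangle$
is implemented over a deliberately minimal molecular-mechanics backend:
per-element 12-6 Lennard-Jones parameters, per-atom charges (zero unless
supplied), Coulomb electrostatics with
$k_e = 332.06\ \mathrm{kcal\,Å\,mol^{-1}e^{-2}}$, an HCT-style
pairwise-descreening generalized-Born term, and the nonpolar surface term
$\sigma \cdot \mathrm{SASA}$ with
$\sigma = 0.0072\ \mathrm{kcal\,mol^{-1}Å^{-2}}$. The point of this
backend is that the combination equations, their bookkeeping identities
and the scanning protocol are exactly testable on toys; no claim of
force-field fidelity is made, and reproducing absolute published energies
for real inhibitors is out of scope.

Within the single-trajectory protocol the gas-phase terms are computed as
the exact intermolecular cross sums (complex minus isolated species at
identical frame coordinates), which makes the internal-energy difference
vanish by construction — the same neglect the single-trajectory protocol
makes — and keeps the non-interacting-ligand limit exact. Isolated species
are minimized (steepest descent, adaptive step, 1000-step budget or
gradient below 0.01 kcal mol⁻¹ Å⁻¹) before the solvation and entropy
terms only. Entropy, when requested, combines Sackur–Tetrode
translational and rigid-rotor rotational closed forms at 300 K with
harmonic vibrational entropy from the mass-weighted Hessian of the
gas-phase terms (central differences of the analytic gradient) on
minimized average structures; more than six near-zero eigenvalues flags an
unminimized system and is an error.

Alanine scanning truncates the side chain beyond C$\beta$ on every
wild-type frame — a C$\gamma$, when present, becomes a hydrogen at 1.09 Å
along the C$\beta$–C$\gamma$ bond; the unified single-pseudo-atom side
chains of toy structures are removed entirely, since they stand for
everything beyond C$\beta$ — then minimizes only the mutated side chain
with the rest fixed and recomputes the terms.
$\Delta\Delta G = \Delta G^{\mathrm{mut}} - \Delta G^{\mathrm{WT}}$ is
averaged over frames with the entropy term omitted. Scanning an alanine is
the identity mutation and reports exactly zero; glycine and proline have
no canonical C$\beta$ truncation and are skipped with a recorded reason.

# Synthetic study systems

The generators are pure functions of their specification plus an integer
seed (R's global RNG state is saved and restored around every call).

* `gen_toy_structure()` builds ideal-geometry N/CA/C backbones (NeRF
  construction with standard bond lengths and angles; helical torsions give
  the canonical 3.8 Å CA–CA spacing) with one pseudo side-chain atom
  (`CB2`) per non-glycine residue, so contact counts stay small,
  hand-checkable integers.
* `gen_ensemble()` displaces residues along selected ANM modes with
  Gaussian amplitudes, optionally plus independent per-residue noise. The
  target variance of the projection onto mode $k$ is the squared amplitude,
  which the suite verifies by Monte-Carlo. Selecting a rigid-body mode is
  an error.
* `gen_msa()` plants conserved columns (emit a fixed residue with stated
  probability) and coevolving pairs drawn, with probability equal to the
  coupling, from a shared two-state paired alphabet. The paired-alphabet
  model was chosen over Potts sampling precisely because it has closed-form
  targets: a fully coupled pair has MI exactly $\ln 2$ in the
  infinite-sample limit, so recovery tests assert analytic truth rather
  than another simulation.
* `gen_complex()` builds a two-lobe dumbbell: each lobe is a Fibonacci
  sphere of residues with two-atom pseudo side chains pointing at the lobe
  centroid (so neighbouring residues share several atom pairs and clear the
  3% admission threshold), the lobes meet through a single engineered
  bottleneck contact above a 14 Å cleft, and the ligand is a chain of atoms
  spanning the cleft that touches every pocket residue within 4.5 Å and no
  other residue — verified at generation time, with an error otherwise.
  `bridge_strength = 0` parks the ligand more than 20 Å away as a
  non-interacting control. Holo and apo protein coordinates are identical.

What these systems do **not** emulate: realistic packing density and
side-chain rotamers, solvent structure, anharmonic or multi-basin dynamics,
phylogenetic correlation between sequences, and chemically meaningful
ligand topology. Passing tests therefore demonstrate that the statistics,
graph algorithms and energy bookkeeping are implemented correctly and
recover planted signals under the stated noise models — not that any
biological conclusion about a particular kinase would be reproduced from
real trajectories.

# Numerical choices and problem sizes

* Contact cutoffs are inclusive (`<=`); the 4.5 Å, 3.0%, 6.5 (z-scale) and
  5 Å defaults are carried in one place (`default_config()`) and mirrored
  by every function signature.
* Shortest-path tie tolerance: relative $10^{-9}$; correlation clamp
  $[10^{-6}, 1-10^{-6}]$; betweenness validated to $10^{-12}$ against
  enumeration.
* Laplace pseudocounts for MI are available but off by default so the hand
  examples are exact.
* The default suite runs at desk scale chosen to keep the full test run
  within a few minutes on one core: alignments of 2000 sequences by 50
  columns for recovery tests, ensembles of a few hundred to 5000 frames
  for sampling-error bounds, complexes of 16–24 residues, 120–960 SASA
  quadrature points depending on the tolerance being exercised, and
  pipeline demos of 10–40 frames with 30–50 permutations. Entropy frame
  subsampling defaults to at most 50 frames.

# Pipeline and provenance

`run_pipeline()` executes the stages in dependency order from a YAML
configuration (every flag mirrors a config key), performs a pre-flight
check of stage inputs before any computation, logs progress to stderr, and
writes deterministic TSV/JSON/GraphML outputs plus a `provenance.json`
holding the full configuration, its hash and the seed. Identical
configuration and seeds reproduce byte-identical outputs, which the
acceptance suite asserts. Figures are deliberately left out of the core
outputs — every plot in the package (`autoplot()` methods,
`plot_joint_profiles()`) is reproducible from the written tables.

# Known limitations

* Dataset-mode normalization factors depend on the input set; small inputs
  give noisy $N_i$ and thus threshold sensitivity near $I_{\min}$.
* The pooled permutation null is miscalibrated when column alphabets are
  strongly heterogeneous; use `pooled = FALSE` there.
* The GB term uses one descreening parameter set for all atoms; it is a
  functioning generalized-Born implementation, not a tuned solvation
  model.
* Harmonic vibrational entropy requires a bonded topology that constrains
  all internal degrees of freedom; loosely connected toy ligands should be
  scanned with `entropy = "none"` (the default).
* The SASA quadrature is deterministic in the laboratory frame, so areas
  are exactly reproducible but rotationally invariant only to quadrature
  accuracy (~1–2% at 240 points, better at 960).
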