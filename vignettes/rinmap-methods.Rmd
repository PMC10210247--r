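---
title: "Residue interaction network fingerprints and autoencoder maps: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue interaction network fingerprints and autoencoder maps: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rinmap)
```

## The model

rinmap treats a protein molecular-dynamics trajectory as a *temporal network*:
every frame is translated into a residue interaction network (RIN), an
undirected, unweighted graph whose nodes are the amino-acid residues in
sequence order. Two residues are connected when the smallest distance between
any of their atoms is below a cutoff of 6 Å, except for directly neighboring
residues in the sequence, which are always in contact and carry no
information. The graph topology of each frame is then summarized by the
**closeness centrality** of every residue,

$$c_i \;=\; \frac{N-1}{\sum_{j \ne i} d(v_i, v_j)},$$

the reciprocal of the mean shortest-path length (in hops) from residue $i$ to
all other residues. Central residues — those buried in a well-packed core —
have high closeness; dangling tails have low closeness. The $N$ closeness
values, ordered by sequence, form a per-frame *closeness fingerprint*, and the
$m \times N$ fingerprint matrix (max-normalized to $[0,1]$ over all frames) is
the feature set for dimensionality reduction.

The embedding is a neural-network autoencoder with a
multidimensional-scaling-like pairwise-distance cost. The encoder maps the
$N$-dimensional fingerprint through hidden layers to a 2-d bottleneck; the
decoder maps back. Training minimizes

$$C \;=\; w_{auto}\,C_{auto} + w_{dist}\,C_{dist} + w_{center}\,C_{center} + \lambda \sum \|W\|_2^2,$$

where $C_{auto}$ is the mean squared reconstruction error, and

$$C_{dist} \;=\; \Big\langle \big(s_h(R_{ij}) - s_l(r_{ij})\big)^2 \Big\rangle_{i<j}$$

compares sigmoid-transformed Euclidean pair distances between frames in the
high-dimensional fingerprint space ($R_{ij}$) and the 2-d map ($r_{ij}$). The
sigmoid

$$s(r) = 1 - \big(1 + (2^{a/b}-1)(r/\sigma)^a\big)^{-b/a}$$

satisfies $s(0)=0$, $s(\sigma)=\tfrac12$ and $s(\infty)=1$: distances much
smaller or much larger than $\sigma$ are compressed, so the map concentrates
on intermediate-scale structure instead of trying to reproduce all distances
(the Sketch-map idea). $C_{center}$ is a small penalty on squared latent
coordinates that keeps the map centered at the origin.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 6.0 Å | contact criterion on the minimum inter-atomic distance (strict `<`) |
| `neighbor_exclusion` | 1 | exclude \|i−j\| ≤ 1 sequence pairs (same chain only) |
| `sigma_h, a_h, b_h` | 0.5, 6, 6 | sigmoid for fingerprint-space distances |
| `sigma_l, a_l, b_l` | 1, 2, 6 | sigmoid for map-space distances |
| `learning_rate` | 1e-5 | Adam step size |
| `regularization_const` | 1e-5 | L2 weight penalty |
| `n_steps`, `batch_size` | 2000, 256 | training length and mini-batch size |
| `hidden_widths` | 128, 128, 128 | tanh hidden layers (mirrored in decoder) |
| `w_auto, w_dist, w_center` | 1, 500, 1e-4 | cost weights |

Two sigmoid presets are shipped: `sigmoid_preset("minipro")`
(σ<sub>h</sub> = 0.5, for ~20-residue mini-proteins whose normalized
fingerprints move on that scale) and `sigmoid_preset("twodomain")`
(σ<sub>h</sub> = 1.0, for larger multi-domain proteins). The approach is
fairly robust to the cutoff as long as the graphs stay connected; for frames
whose RIN disconnects (fully extended conformations), closeness switches to
the Wasserman–Faust component-scaled form
$c_i = \frac{r_i-1}{N-1}\cdot\frac{r_i-1}{\sum d}$ (with $r_i$ the reachable
set size), which coincides with the standard formula on connected graphs and
assigns 0 to isolated nodes. A strict mode (`disconnected = "error"`) is
available when disconnection should abort a run instead.

### Design choices where the design was open

* **Closeness normalization.** "Normalized by the number of nodes" admits two
  readings: the $(N-1)/\sum d$ reachability normalization used by the common
  network toolkits (our default, `scale = "standard"`), or an additional
  global $1/N$ factor (`scale = "per_node"`). They differ by a constant, and
  the subsequent max-normalization of the fingerprint matrix cancels the
  difference entirely, so embeddings are invariant to the choice; only raw
  fingerprint values differ.
* **Strict cutoff boundary.** The criterion is $d <$ cutoff; equality is a
  measure-zero event for real coordinates and is excluded deliberately so the
  convention is unambiguous.
* **Hydrogens.** All atoms enter the minimum-distance search by default
  ("any two atoms"); `heavy_only = TRUE` is offered because many archived
  trajectories strip hydrogens, which systematically shifts minimum distances
  upward by fractions of an Å.
* **Pair-cost prefactor.** $C_{dist}$ averages over in-batch pairs rather
  than summing, so the cost (and the gradient scale) is independent of batch
  size. Pairs are subsampled through mini-batching — all pairs *within* each
  batch — which is what makes $10^5$–$10^6$-frame datasets tractable; with
  `batch_size >= m` the full pair set is used every step (the mode the small
  validation runs use).
* **Indexing.** Residue indices are 1-based sequence positions throughout,
  matching R and every package rinmap builds on; user-facing output uses
  author numbering via the residue labels.
* **Vertical shift** uses Cα atoms as the residue anchor (the conventional
  choice when no atom is specified), and **helix RMSD** superposes on the
  helix selection itself so helix formation is detected independent of global
  orientation. RMSD-type variables default to backbone atoms (N, CA, C, O).
* **Storage formats.** Feature matrices persist as CSV with a JSON metadata
  sidecar (cutoff, normalization flag); model checkpoints are self-describing
  JSON holding every weight at full precision. Both are plain text and
  round-trip exactly enough to reproduce projections bit-for-bit.

## Numerical notes

* Shortest paths on the unweighted RIN are integer hop counts (BFS, via
  igraph); unreachable pairs are flagged `NA`, never a large sentinel.
* The autoencoder is trained with Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
  $\epsilon = 10^{-8}$) and Glorot-uniform initialization. A single seed
  controls initialization and batch sampling; runs are bit-reproducible on
  fixed hardware, while cross-platform floating-point reductions may differ
  in the last bits.
* The gradient of $C_{dist}$ with respect to a latent point involves
  $1/r_{ij}$; coincident map points are handled by the analytic limit — with
  $a_l > 1$ the sigmoid's slope vanishes at 0 faster than $1/r$ diverges, so
  the contribution is set to 0.
* Kabsch superposition uses the SVD with a determinant correction restricting
  the solution to proper rotations. Point sets with fewer than 3
  non-collinear points (e.g. a perfectly straight chain) admit no *unique*
  optimal rotation, but the minimal RMSD value is still well defined — the
  rotational freedom lies in a zero-residual direction, and the determinant
  correction acts on a zero singular value at no cost — so the fitted value
  is returned with a warning about the non-uniqueness.
* Periodic boundary conditions are **not** unwrapped anywhere: input frames
  must contain whole, centered molecules, as standard trajectory
  post-processing produces.

## What the synthetic generator emulates — and what it does not

`toy_two_state_trajectory()` produces a single-atom-per-residue chain that
switches between a *compact* state (an ideal helix, radius 2.3 Å, rise
1.4 Å/residue, 100°/residue twist, chosen so sequence-separation 2–4 pairs
fall under the 6 Å cutoff) and an *extended* state (a straight chain at
3.8 Å Cα spacing, whose closest non-neighbor pairs sit at 7.6 Å and form no
contacts), with Markov switching (`p_switch = 0.02` per frame) and isotropic
Gaussian jitter (`noise_sigma = 0.3` Å). The defaults — 20 residues, 2000
frames — mirror the size of a fast-folding mini-protein and a desk-scale
trajectory length.

This emulates exactly the property the workflow exploits: low-contact (open)
and high-contact (closed) states with distinct contact topologies and hence
distinct closeness fingerprints. It does **not** emulate gradual folding
pathways, metastable intermediates, realistic side-chain packing, or
force-field thermodynamics. A passing two-state separation test therefore
demonstrates that the pipeline — contact graphs → closeness fingerprints →
sigmoid-cost embedding — resolves discrete contact-topology states; it does
not certify resolution of subtler conformational substates in real data.

The problem sizes used in the validation suite (20 residues, up to 2000
frames, 2000 training steps) are the package's reference configuration for a
laptop-scale run; all of them scale up linearly in frames.

## Worked example

```{r example, eval = FALSE}
toy <- toy_two_state_trajectory(toy_trajectory_spec(seed = 1))
fp  <- featurize_trajectory(toy$trajectory, toy$topology)   # 2000 x 20
model <- train_encodermap(fp, encodermap_config(seed = 1),
                          sigmoid_preset("minipro"))
pmap <- project_map(model, fp)
pmap <- add_cv(pmap, "rg", cv_series(toy$trajectory, toy$topology,
                                     cvs = "rg")$rg)
plot_map(pmap, "rg", "map_rg.png")
```

The same pipeline runs from the shell:

```sh
rinmap simulate  --out toy.pdb --frames 2000 --seed 1
rinmap run-all   --topology toy.pdb --out-dir run1 --seed 1
rinmap run-all   --manifest run1/manifest.json --out-dir run2   # exact replay
```

Every `run-all` writes a `manifest.json` recording the full configuration,
seed and package version; replaying it reproduces the feature matrix
byte-identically and the projection deterministically.

## Known limitations

* Trajectory input is multi-model PDB and DCD; GRO/XTC readers are not
  provided (no R reader exists for these formats), so nm-based formats must
  be converted upstream.
* Closeness is computed exactly; for proteins with thousands of residues an
  approximate algorithm would be preferable, and the centrality step is the
  natural plug-in point (any function mapping a `residue_graph` to an
  N-vector can replace `closeness_centrality` in a custom featurizer).
* Alternative centralities (betweenness, eigenvector) and alternative
  embedders (PCA, UMAP) are deliberately out of scope; the fingerprint
  matrix is an ordinary numeric matrix and can be handed to any external
  embedding tool.
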