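---
title: "Fixed-backbone sequence design with contact-map graph networks"
author: "cgraphdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-backbone sequence design with contact-map graph networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Fixed-backbone protein design (inverse folding) asks for an amino-acid
sequence expected to fold into a given backbone.  `cgraphdesign`
implements a graph neural network for this task in which the protein
graph is a *contact map*: two residues are connected whenever their
virtual C-beta atoms lie within a distance cutoff (12 Å by default), so
the neighbor count adapts to local packing density instead of being fixed
as in a k-nearest-neighbor graph.  The virtual C-beta is a pseudo
side-chain atom computed from backbone geometry alone,

$$r_{C\beta} = -0.58273431\,u + 0.56802827\,v - 0.54067466\,(u \times v) + r_{C\alpha},$$

with $u = r_{C\alpha} - r_N$ and $v = r_C - r_{C\alpha}$; it is defined
for every residue, glycine included.

The network stacks ten blocks (by default) that update **edge states
first** and node states second:

* *basic edge update*: $\hat e_{ij} = \mathrm{MLP}(h_i \,\|\, e_{ij} \,\|\, h_j)$;
* *symmetric branch*: each edge is concatenated with its reverse edge,
  $\hat e^{sym}_{ij} = \mathrm{MLP}(\hat e_{ij} \,\|\, \hat e_{ji})$ —
  only meaningful in contact-graph mode, where both directions always
  exist;
* *second-order branch*: for every shared neighbor
  $n \in N_i \cap N_j$, the edge pair $(\hat e_{in}, \hat e_{nj})$ is
  composed with $\hat e_{ij}$ through an MLP and averaged over $n$; an
  edge with no shared neighbors contributes a zero vector;
* the branches (plus a plain MLP refinement $\hat e^2_{ij}$) are merged
  by a **selective kernel**: a squeeze MLP on the branch sum feeds
  per-branch excitation MLPs whose outputs are softmax-normalized across
  branches, per feature dimension, giving a learned per-dimension gate;
* the node update combines a single-head graph attention over
  in-neighbors (queries from the node state, keys from the updated edge
  states, values from the node/edge concatenation, raw dot-product
  logits) with a global context vector (per-dimension softmax over all
  nodes of the structure), again merged by a selective kernel;
* residual connections, layer normalization and position-wise
  feed-forward wrappers follow each update; the first node residual
  deliberately carries no dropout, unlike the edge residual.

The output head emits one-shot 20-class logits for every unmasked
residue: no autoregression, so design of a whole chain is a single
forward pass.

Input features are rotation- and translation-invariant by construction:
all vectors are expressed in per-residue orthonormal frames
$Q = [b, n, b \times n]$ with $b \propto u - v$, $n \propto u \times v$;
distances enter through 16 Gaussian radial basis functions with centers
evenly spaced on [2, 22] Å and width equal to the spacing; relative
orientations enter as unit quaternions of $Q_i^\top Q_j$ (sign fixed by a
non-negative scalar part); and sequence separation $i - j$ enters through
a 16-dimensional sinusoidal encoding, signed and unclipped.  Each edge
also carries the 8 × 8 RBF-encoded distance table between five backbone
atoms (N, Cα, C, O, virtual Cβ) and three *learnable* virtual atoms
placed at $x u + y v + z (u\times v) + r_{C\alpha}$ with
$x^2 + y^2 + z^2 = 1$; the constraint is enforced by projection onto the
unit sphere at every evaluation and gradients flow through both the
projection and the radial basis encodings.  The edge feature vector is
75 + 1024 + 4 + 16 = **1119**-dimensional under the defaults.

The node feature blocks are the four frame-relative unit vectors from Cα
to N, C, O and the virtual Cβ (12 dims), sin/cos of the three backbone
bond angles and of ω, φ, ψ (12 dims), and the four RBF-encoded Cα–atom
distances (64 dims) — 88 dimensions in total, recorded in the feature
metadata.  Angle features that need residue $i-1$ or $i+1$ (termini, or
a masked neighbor) are zero-filled in both the sine and cosine slot,
which is the inert value for a jointly-read sin/cos pair.  Residues
missing any of the four backbone atoms are masked: excluded from the
graph, the features and the loss, with `NA` sentinel rows in the output.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 12 Å | contact-graph distance cutoff (8/10/12 studied; boundary inclusive) |
| `k` | 30 | neighbor count of the alternative KNN graph |
| `hidden` | 128 | width of node and edge states in every block |
| `n_blocks` | 10 | number of edge+node update blocks |
| `dropout` | 0.1 | all dropout operators during training |
| `max_lr` | 0.004 | OneCycle peak learning rate (AdamW) |
| `batch_residues` | 4096 | maximum residues per training batch |
| `noise_sd` | 0 (option 0.02 Å) | Gaussian coordinate-noise augmentation |

With the defaults the model holds about 7.8 M parameters
(`count_params(cgnn_init(cgnn_config()))`).  Closely related published
models of this family are quoted around 5.6 M; exact counts depend on
choices that this package fixes uniformly and documents here:
every unlabeled "MLP" is two affine layers with one
smooth gating nonlinearity (the sigmoid form of the Gaussian-error linear
unit) and hidden width equal to the model width, the input projections
are a single affine map plus layer normalization, and the selective
kernel uses full-width squeeze and excitation MLPs.  Parameter count is a
pure function of the configuration and is printed by `describe_model()`.

Ablation variants are pure configuration (`ablation_config()`): variant
`model1` removes both the symmetric and second-order edge branches,
`model2`/`model3` keep exactly one of them, and `model4`–`model6`
replace selective kernels by average pooling in both, only the edge, or
only the node updates.  KNN mode refuses the symmetric branch with an
actionable error, because reverse edges are not guaranteed to exist.

## Design decisions where the description was open

* **Selective-kernel normalization.**  An excitation of the form
  $a_i = w_i / \sum \exp(w_i)$ is not a normalized weighting; the
  package uses the softmax $\exp(w_i)/\sum\exp(w_i)$, as in the
  original selective-kernel networks.  The per-branch weights then sum
  to one per dimension, which the tests assert to 1e-6.
* **Attention scaling.**  Attention logits are raw dot products with a
  single head; `attention_scale` adds the $1/\sqrt{d}$ factor but is
  off by default.
* **Quaternion convention.**  The relative rotation is
  $Q_i^\top Q_j$ in the frame of the receiving residue, components
  ordered (w, x, y, z), sign fixed by $w \ge 0$; a round-trip test
  against the rotation matrix pins the convention down.
* **Graph boundary.**  Pairs at exactly the cutoff distance are
  connected (closed ball); KNN distance ties break toward the lower
  residue index so construction is deterministic.
* **Node feature total.**  Descriptions of this feature layout
  sometimes quote 96 node dimensions, but the blocks enumerated above
  total 88 and no decomposition of the remaining 8 is recoverable; the
  package implements the enumerated 88 and records the dimension in
  metadata rather than pad silently.
* **Virtual-atom parameters** are shared across blocks, initialized
  uniformly on the unit sphere under a fixed seed, and re-projected at
  every evaluation.

## Training

Training minimizes the mean categorical cross-entropy (natural log, no
label smoothing) of native residues under the predicted logits, with
AdamW (decoupled weight decay 0.01, β = 0.9/0.999) and a OneCycle
schedule that warms up over the first 30 % of steps from `max_lr`/25 to
exactly `max_lr` and cosine-anneals to `max_lr`/10⁴; warm-up fraction
and divisors are fixed at these common defaults and echoed in every
checkpoint.  Structures are randomly
packed into batches of at most `batch_residues` residues per epoch; a
batch runs as one disjoint-union graph (attention groups and the global
context are segmented per structure, so batched logits are bit-equal to
per-structure logits, which a test asserts).  Gradients come from an
in-package reverse-mode tape over dense matrices; every operator and the
end-to-end network gradient are checked against central finite
differences.  Mixed precision is not used: determinism at desk scale
matters more, and two runs with one seed reproduce the final loss to
1e-6.  Optional augmentation re-generates features each epoch after
adding Gaussian coordinate noise (0.02 Å is the studied level).

## What the synthetic generator emulates — and what it does not

`make_backbone()` builds single chains from ideal internal coordinates
(N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å, standard bond angles, ω =
180°; helix φ/ψ = −57°/−47°, strand −119°/+113°, coil torsions drawn
uniformly from the broad allowed region under the spec seed).  It
produces realistic local geometry and, through mixed segments, diverse
contact environments, which is exactly what the featurization and graph
code consume.  It does **not** emulate side chains, chain breaks,
Ramachandran-weighted coil sampling, tertiary packing optimized for
compactness, or crystallographic artifacts, so green tests here say the
machinery is correct on well-formed single chains — not that the model
reaches any particular recovery on real proteins, which requires
GPU-scale training on a curated structure corpus and is out of scope.

`label_sequence()` attaches a deterministic geometry-to-sequence rule
(amino-acid index = virtual-Cβ neighbor count at 12 Å, mod 20).  Because
the label is a function of the very contact graph the model consumes,
a small model must be able to fit it; the learnability benchmark trains
2 blocks × width 64 for 300 epochs on ten ~30-residue structures with a
128-residue batch budget (chosen so each epoch takes several optimizer
steps at this scale) and reaches ≥ 95 % training recovery on one CPU in
minutes.  These sizes are the package's fixture conditions, stated here
once and used identically by `learnability_dataset()`, the tests and the
command line.

## Evaluation battery

* **Perplexity**: exponentiated residue-pooled mean negative log
  probability of native residues (1 = perfect, 20 = uniform); equals
  `exp(loss)` of the training objective by construction, asserted to
  1e-6.
* **Recovery**: percent identity of the argmax design; dataset summary
  is the median over structures (pooled recovery also reported).
* **Composition**: relative deviation |X−X′|/X of pooled amino-acid
  frequencies, median over the 20 types; types absent from the natives
  are flagged, not divided by zero.
* **Substitution plausibility**: log₂ odds confusion matrix
  s(x,y) = log₂ p(x,y)/(q(x)q(y)) with a pseudocount of 1 on the
  pair-count table, Pearson-correlated against the embedded BLOSUM62;
  plus the probability-weighted BLOSUM score, and its relative form that
  equals exactly 1 for native predictions.
* **Low-complexity regions**: two-pass sliding-window scan (window 12,
  trigger entropy 2.2 bits, extension 2.5 bits, minimum
  composition-probability refinement); the fraction of residues inside
  detected segments is the LCR %.
* **Hydrophobicity conservation**: fraction of positions whose designed
  residue keeps the native two-way class (hydrophobic
  I,L,M,F,C,W,P,V,A,G vs hydrophilic S,T,N,Q,D,E,H,R,K,Y); the joint
  value is the headline and a per-class breakdown is reported.
* **Core/surface split**: Shrake–Rupley SASA (probe 1.4 Å, 192-point
  deterministic golden-spiral grids, backbone atoms plus virtual Cβ as a
  minimal side-chain proxy) normalized by the theoretical maximum
  accessibility per residue type; RSA < 0.2 is core, the boundary value
  is surface.  Because the point grid does not rotate with the molecule,
  numerical SASA varies by a percent or two under rigid motion; the
  classification is what is invariant.
* **Structure deviation**: Kabsch RMSD (SVD with proper-rotation sign
  correction) and GDT-TS over cutoffs 1/2/4/8 Å.  The GDT superposition
  search is a documented approximation of the full local-global
  alignment: the all-residue fit plus every contiguous 7-residue seed,
  each refined by iteratively re-fitting on residues inside the cutoff;
  it is exact on the analytic fixed points the tests use and is not
  claimed identical to the reference LGA search.

## Numerical choices and degenerate inputs

Layer-norm ε is 1e-5; softmaxes subtract per-group maxima; zero native
probabilities in perplexity are clamped at 1e-12 with a warning;
degenerate frames (‖u−v‖ or ‖u×v‖ < 1e-8) fall back to the identity with
a flag; an isolated node receives a zero local-attention vector and
still gets a finite update through the global branch; a structure whose
residues are all masked is rejected.  Problem sizes throughout the test
suite (structures of 8–50 residues, 50-structure graph-oracle sweeps,
100-sequence low-complexity comparisons) are the package's desk-scale
defaults.

## Known limitations

Single chains only (first model of multi-model files, no ligands or
nucleic acids); no autoregressive or constrained design; the KNN
baseline excludes masked residues before neighbor selection; headline
benchmark numbers from the reference corpus are not reproducible at this
scale and are not claimed — the acceptance artifacts instead verify the
documented feature dimensionality, the virtual-Cβ arithmetic, invariances,
oracle equalities, analytic metric fixed points and learnability.
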