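---
title: "Multi-view molecular representations with gated late fusion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view molecular representations with gated late fusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

molfuse represents a small molecule through three complementary views and
combines them at the output stage.

**Graph view.** The heavy-atom molecular graph $G = (V, E)$ is treated as a
sequence of $|V| + |E|$ tokens: one per atom and one per bond. Each atom
token carries five categorical features (atomic number, chirality, degree,
formal charge, hybridization); each bond token carries five (bond type,
bond direction, double-bond stereo, conjugation, ring membership). Every
categorical feature is embedded separately (width 128 at the default
configuration) and the concatenation is projected to the token width (512
by default). Structural position comes from the spectral decomposition of
the combinatorial Laplacian $L = D - A$: the $k$ smallest eigenpairs are
attached to each token — a node token uses its own eigenvector row twice, a
bond token the rows of its two endpoints — and projected into the token
space. A standard pre-norm transformer runs over the tokens and the output
is mean-pooled.

**Image view.** The molecule is drawn from its 2D coordinates as bond line
segments plus element-colored atom disks on a white 256x256 canvas, cropped
to 224x224 (central crop at evaluation, seeded random crop plus random
horizontal flip during training), and normalized per channel with fixed
constants. A small residual CNN (strided stem, one identity block, one
strided block with projection skip, global average pooling) encodes the
grid.

**Text view.** The SMILES string is tokenized by a regular expression whose
alternatives are bracket atoms, two-letter halogens, aromatic/organic
subset atoms, bond and branch symbols, and ring-closure digits (including
`%nn`). The concatenation of the surface tokens always reproduces the
input, which the tests assert on every generated molecule; spans the
pattern does not cover become `<unk>` tokens with a warning rather than a
failure. Token ids are embedded (768-wide by default), given sinusoidal
positions, and passed through a transformer; padding tokens are excluded
from both attention keys and the mean pooling.

## Gated late fusion

Per-view embeddings $z_{im}$ for molecule $i$ and view $m$ are combined by
a batch-level attention gate:

$$ w_m = \frac{1}{B}\sum_{i \in B} q^\top \tanh\!\big(W \tfrac{z_{im}}{\lVert z_{im}\rVert_2} + b\big), \qquad
   \alpha = \operatorname{softmax}(w), $$

$$ z^{mv}_i = \mathrm{MLP}\Big(\sum_m \alpha_m z_{im}\Big). $$

The normalization inside the gate makes $\alpha$ invariant to per-view
rescaling of the embeddings, and the softmax makes it invariant to additive
shifts of the scores; both properties are exercised as tests. Because
$w_m$ is a batch mean, single-molecule inference would depend on batch
composition; the implementation therefore freezes $w$ at the value recorded
on the training batch of the selected model and reuses it for all
predictions. This is a deliberate design choice in favor of deterministic
screening output.

The MLP in the fusion head has two layers (tanh hidden layer of the
embedding width); the reconstruction pre-training of the aggregator
attaches one linear head per view mapping $z^{mv}$ back to that view's
input embedding under mean squared error. On synthetic triples where two
views share a latent signal and the third is independent noise, the gate
learns to down-weight the noise view — the test suite runs that experiment
at three seeds. Three alternative fusion schemes (projected gating,
unprojected gating, projected gating with feature addition) are provided
with their gate-input dimensionalities $D = 3\min(d_i)$ and
$D = \sum d_i$ respectively.

Reference gate weights of (0.6, 0.3, 0.1) for (image, graph, text),
recorded after reconstruction pre-training at foundation scale, are kept as
the constant `alpha_pretrained_reference` for comparison; desk-scale
pre-training on synthetic embeddings is not expected to reproduce them, and
the package makes no such claim.

## Self-supervision targets

* **Token masking** (text): a uniformly random 15% of maskable tokens.
* **Feature masking** (graph): 85% of the node+edge tokens jointly; masked
  features are replaced by a per-feature sentinel embedding row. Replacing
  rather than randomizing was chosen because the masking objective predicts
  the original category — a sentinel makes the corruption unambiguous.
* **Edge corruption** (graph): 15% of edges have one endpoint rewired to a
  uniformly chosen different node; the bond feature vector is kept, only
  the connectivity lies. Per-edge binary labels mark corrupted vs original.
* **Betti targets** (graph): for every node $v$, the induced subgraph
  $S_v$ on nodes within $k$ hops yields $\beta_0(S_v)$ (connected
  components) and $\beta_1(S_v) = |E| - |V| + \beta_0$ (independent
  cycles). The default radius is $k = 2$ with induced-subgraph semantics:
  two hops are the smallest neighborhood that sees complete 5- and 6-rings
  from most member atoms while keeping targets local. Targets used as
  class labels are clipped at a configurable maximum (default 8); raw
  values are always retained. Whether the original objective was framed as
  regression or classification is not stated in the source method; both
  consumptions are possible from the emitted targets.

All masking/corruption counts use round-half-away-from-zero of
rate x n, with empty plans for degenerate graphs (fewer than two nodes, or
no rewiring candidate).

# Chemistry backend

Parsing, canonicalization and the physicochemical descriptor block
(molecular weight, H-bond donors and acceptors, logP, TPSA) go through
Open Babel via ChemmineR/ChemmineOB; canonical SMILES therefore follow
Open Babel's canonical atom order. Molecular graphs — elements, bond
orders, aromaticity, hybridization types, formal charges, 2D coordinates —
are read from Open Babel MOL2 output through a small vectorized reader,
since no installed R package exposes per-atom/per-bond detail from MOL2.
Rotatable bonds are counted on the graph (acyclic single bonds between
non-terminal heavy atoms, excluding triple-bond neighbors — the standard
default definition). Substructure tests use igraph's LAD matcher with
element+charge vertex domains; bond orders are not compared, which is
sufficient for the charged nitro marker used by the synthetic tasks.

Murcko scaffolds are computed by iteratively pruning terminal atoms from
the kekulized graph (ring systems and linkers survive), restoring atoms
attached to the framework by multiple-order bonds (e.g. exocyclic
carbonyls), and re-canonicalizing the framework through Open Babel.
Acyclic molecules get the empty scaffold key and form singleton clusters,
one per unique molecule — the representation the splitting code relies on.
Largest-fragment selection breaks ties by molecular weight, then by
lexicographically smallest canonical SMILES, so curation is deterministic.
Duplicate detection happens after canonicalization.

# Splitting and evaluation

Three split methods are provided. *Random* permutes records by seed and
slices to the exact target counts — the deterministic-fraction variant of
a random split, chosen over per-record multinomial draws so that partition
sizes are reproducible and exact. *Size-ordered scaffold* sorts scaffold
clusters by descending size and fills train to capacity, then validation,
then test; a cluster that fits nowhere falls back to train. *Balanced
scaffold* forces clusters larger than the test-partition target into
train and distributes the shuffled remainder to test, validation, then
train. In both scaffold methods clusters are atomic, so no scaffold key
can span two partitions; the acceptance suite checks this leak-freedom on
100 seeded datasets.

Regression metrics can be placed on a common axis with
$m' = 1 - (m - m_0)/s$ using the registry pairs (ESOL (0.7, 1.0),
FreeSolv (1.5, 5.0), Lipophilicity (0.50, 1.0), QM7 (55.0, 100.0),
ComputationalADME (0.30, 1.0)); the transform is affine and invertible.

Fine-tuning trains the per-view output projections, the gate, and the MLP
head with full-batch Adam under up to four learning-rate groups (one per
view, one for aggregator+head), early stopping on validation loss
(patience 10, at most 100 epochs), across five seeds; the reported metric
is the seed mean with a 95% t-interval, and the returned model is the
highest average-validation performer. The encoder backbones themselves are
frozen random-initialized feature extractors at desk scale: every
architectural element is present and differentiable where trained, but
full backbone backpropagation is deliberately out of scope — the learning
experiments the package supports (substructure classification, descriptor
regression, latent-affinity recovery) are solvable from the pooled
backbone features, and the tests demonstrate exactly that.

Model agreement uses the asymmetric F1 of one model's binarized
predictions against the other's (threshold 0.5 on sigmoid scores) for
classification, and Pearson correlation with a chi-squared p-value
($n r^2 \sim \chi^2_1$ under the null) for regression.

The DTI head projects ligand features and externally supplied protein
embeddings to 64 dimensions each, concatenates to 128, and applies a tanh
MLP. "Gradual unfreezing" is implemented as a staged schedule: the head
trains alone for the first 20% of epochs, after which the projections
unfreeze. Sixfold cross-validation permutes pairs once by seed into six
equal blocks; fold $f$ tests on block $f$, validates on the next block,
trains on the rest, so every pair is tested exactly once; fold metrics are
averaged arithmetically.

# The synthetic-data generator

The generator emulates a small drug-like screening library: twelve ring
templates with distinct Murcko frameworks (benzene, pyridine, a diazine,
furan, thiophene, pyrrole, naphthalene, indole, cyclohexane, piperidine,
biphenyl, quinoline), decorated at one site with a chain of up to three
carbon linker units and a terminal drawn from 26 common organic
substituents. An acyclic mode produces heteroatom-substituted chains whose
empty scaffolds make every molecule its own singleton cluster. Templates
are used round-robin, so a request of $n \ge$ pool size guarantees at
least pool-size distinct scaffold keys; all output is canonicalized,
deduplicated, and reparses with zero drops (asserted in tests). The
substituent pool deliberately keeps molecules small and drug-like: a
drug-likeness pass retains at least 95% of generated molecules.

Label rules: *substructure_class* marks the presence of a nitro group,
planted during generation with a controlled positive rate (default 0.4)
by grafting the fragment as a branch, and verified structurally — the
label is recomputed from the molecule, not from generator bookkeeping;
*descriptor_regression* is a fixed linear function of molecular weight and
logP plus Gaussian noise (exact when the noise is zero); *latent_affinity*
produces pKI-like values in [4, 10] driven by marker presence, heteroatom
fractions and aromaticity. Problem sizes used by the test and acceptance
suites — 10,000 molecules for rate accounting, 2,000 for the learning
experiment, 500 random graphs for the topology oracle, 360 pairs for DTI
recovery — were chosen as the smallest sets at which the binomial/rounding
tolerances stated for each check are comfortably meaningful.

What the generator does **not** emulate: realistic activity cliffs,
stereochemistry-dependent labels, tautomers, measurement noise structure,
or the property distributions of real vendor libraries. A model passing
the synthetic suites is demonstrated to be mechanically correct and able
to learn recoverable structure-label relationships; nothing here certifies
benchmark-level accuracy on real assay data.

# Numerical conventions

* Laplacian eigenpairs ascend; ties keep the stable order of the symmetric
  eigensolver; each eigenvector's first nonzero component (|x| > 1e-8) is
  made positive; graphs smaller than $k$ are zero-padded.
* Gate normalization rejects zero-norm embeddings explicitly rather than
  adding an epsilon, because a zero embedding indicates an upstream bug.
* Image normalization constants are fixed package constants
  (mean 0.9, sd 0.25 per channel) recorded in `image_norm_constants`.
* All library-internal randomness (augmentation, masking, splits,
  initialization) runs through an explicit seed and restores the caller's
  RNG state afterwards.
* Training is full-batch, so identical seeds reproduce reported metrics
  bit-for-bit; the per-seed metric matrix is part of every report.

# Known limitations

* Open Babel's aromaticity/canonical conventions differ from other
  toolkits; scaffold keys are consistent within the package but not
  string-identical to those of other software.
* The attention heat-map contract exposes head-averaged received-attention
  per token; it is one reasonable choice among several and is validated
  only for its distributional properties (nonnegative, sums to one).
* The regex tokenizer covers standard SMILES; exotic constructs fall back
  to `<unk>` with a warning instead of failing.
* Encoder backbones are not pre-trained; the package generates the
  self-supervision targets and provides the training core, but running a
  large pre-training campaign is out of scope at desk scale.
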