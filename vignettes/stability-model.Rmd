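---
title: "Predicting mutational stability changes with a distance-biased graph transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting mutational stability changes with a distance-biased graph transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutstab)
```

## The problem

A single amino-acid substitution changes the folding free energy of a protein
by an amount ΔΔG (kcal/mol; we use the convention that positive values are
destabilizing). Predicting ΔΔG from structure is the central computational
task of stability engineering, and it is hard for reasons that are mostly
about data rather than models: measurements are scarce, heavily skewed toward
destabilizing mutations (>70%), biased toward alanine substitutions, and
train/test splits in the literature have frequently leaked homologous
proteins across the barrier. `mutstab` implements a complete desk-scale
pipeline that addresses each of these: a structure-based model whose
architecture encodes the thermodynamics, augmentation algorithms that
multiply the data without new experiments, and curation tools that enforce a
homology barrier between splits.

## The model

**Tokens.** The input for one prediction is a *masked microenvironment*: all
atoms within a radius (default 16 Å, configurable) of the target residue's
Cα, with every atom of the target residue removed. Each atom is a token
carrying its element class (C, N, O, S, P, H, other), its partial charge from
a bundled AMBER-style lookup, and its solvent-accessible surface area
computed on the full unmasked structure — features describe the native
environment, not the masked one. Hydrogens are kept if the file has them and
never added; the package does not assign protonation states.

**Distance-biased attention.** The backbone is a transformer over atom
tokens with no positional encoding; all geometric information enters through
an additive attention bias derived from the pairwise distance matrix `D`.
Each `D[i,j]` is encoded by K = 16 Gaussian radial basis kernels
(`exp(-d²/2σ²)`, bandwidths log-spaced over 0.5–20 Å) concatenated with a
C = 4 one-hot distance class (bins at 2.2 / 4.0 / 8.0 Å: covalent, first
shell, mid-range, long-range; boundary values fall in the lower bin), and a
linear map turns the 20 channels into one bias per attention head. The same
bias tensor is added to the pre-softmax logits of every attention layer.
Because tokens are unordered and only distances enter, the architecture is
token-permutation equivariant and rigid-motion (SE(3)) invariant by
construction — both are asserted to 1e-5 in the test-suite rather than
trusted.

**Blocks and classifier.** Element embeddings (width E = 20) are
concatenated with the two physical channels and projected to the token width
H (default 128). Each of the 4 blocks applies two biased attention layers
and one MLP, each sub-layer with pre-layer-normalization and a residual
connection (8 heads, MLP hidden 4H, dropout 0.1 during training). For the
self-supervised task the final-layer states of all tokens within 8 Å of the
masked Cα (the first contact shell) are mean-pooled and passed through a
Linear(128)-ReLU-Linear(20) classifier and a softmax over the 20 amino
acids. At these defaults the model has ~1.08 million parameters (the exact
count is computed and stored on the model object).

**Structural amino-acid embeddings and the ΔΔG head.** After pretraining,
the 20 weight vectors of the classifier's output neurons are reused as
embeddings of the 20 amino acids — each one summarises what the features of
a microenvironment look like when that amino acid sits in it. A mutation is
represented by the ordered pair (from, to) of these embeddings. The
regression head appends one embedding as a CLS token to the backbone's token
states, contextualizes it through its own distance-biased attention blocks
(2 by default; the CLS position has no coordinates, so its bias entries are
zero), and reads back the final CLS state `u`. The two branches share
weights (Siamese); the prediction is

&nbsp;&nbsp;&nbsp;&nbsp;ΔΔG = w · (u_to − u_from)

with the decoder bias fixed at zero by default. This subtraction makes
self-mutations *exactly* zero, predictions *exactly* antisymmetric, and
thermodynamic cycles closed — the state-function property of Gibbs free
energy as an inductive bias rather than a learned regularity. A config
switch (`use_bias = TRUE`) restores a trainable offset for users who want
it. Because one masked microenvironment serves every (from, to) pair, a deep
mutational scan costs one environment build plus 20 branch runs per residue,
not 380; `dms_scan()` caches the 20 contextualized states and recombines
them.

**Sign and order conventions.** ΔΔG is positive-destabilizing and the decode
order is `to − from`. These two choices are arbitrary individually but must
be pinned jointly; they are fixed here and documented on `predict_ddg()`.

## Thermodynamic augmentation

With ΔΔG a state function, the `n` measurements wt→a₁…wt→aₙ characterised at
one position imply the full set of `n(n−1)` ordered mutations among the
mutant amino acids: ΔΔG(aᵢ→aⱼ) = ΔΔG(wt→aⱼ) − ΔΔG(wt→aᵢ). This
*thermodynamic permutation* (TP) set never touches the wild type, is closed
under reversal (so its ΔΔG multiset has mean exactly zero — a balanced
stabilizing/destabilizing split), and satisfies internal additivity exactly.
*Thermodynamic reversibility* (TR) is the simpler swap-and-negate involution.
`augment_dataset()` applies either or both after `dedup_max_abs()`, which
resolves duplicate measurements by keeping the largest |ΔΔG| (ties: first in
input order). Deduplication must precede TP so that `n` counts distinct
mutant amino acids; conflicting wild-type claims at one position abort with
an error rather than silently choosing a reference state.

## Leakage-aware curation

Training proteins within 30% sequence identity of any test protein are
removed — the "twilight zone" threshold below which most protein pairs adopt
different folds. When an MMseqs2 binary is on the PATH the filter shells out
to `easy-search -c 0.3 -s 7.5 --seq-id-mode 1`; otherwise a built-in
Needleman–Wunsch aligner (BLOSUM62, gap open 11 / extend 1, identity =
matches / alignment length) is used, and the report records which backend
ran. The two backends can disagree on short-overlap homologs because of
MMseqs2's coverage mode; `audit_split()` therefore recomputes all cross-split
identities with the built-in aligner after assembly and asserts the barrier
independently of the backend.

## Training

Fine-tuning uses Huber loss (δ = 1), AdamW (β = 0.9/0.999, ε = 1e-8 —
unstated in the source recipe, standard values assumed; no warmup, constant
rate), per-group learning rates (5e-5 head / 2e-5 backbone at full scale),
gradient accumulation (240 × 4 = 960 effective batch), weight decay 0.1, and
an exponential moving average of the weights (η = 0.99) that is used for
all evaluation. The small-dataset recipe freezes the backbone (batch 1024,
500 iterations, lr 5e-7 from a pretrained start or 5e-5 from scratch). The
whole network — attention, layer norm, bias linear, classifier, Siamese head
— is implemented in base R with hand-derived reverse-mode gradients; a test
verifies the analytic gradient of the full forward pass against central
finite differences to 1e-4 relative error, leaf by leaf.

## Synthetic data: what it emulates and what it does not

Everything is testable offline through three seeded, bit-reproducible
generators:

* `make_helix_structure()` builds ideal α-helices (φ = −57°, ψ = −47°,
  standard bond geometry) with one side-chain pseudo-atom (Cβ) per
  non-glycine residue. Pseudo-atoms instead of rotamer libraries: enough to
  exercise distance-dependent attention without a chemistry engine.
* `make_ddg_table()` plants a per-amino-acid potential `g` and emits
  measurements ΔΔG(wt→a) = g(a) + b − g(wt) + ε with a native-bias offset
  b = 1 kcal/mol and Gaussian noise (default sd 0.3 kcal/mol, consistent
  with the ±0.5 kcal/mol experimental-error convention). The offset cancels
  inside TP differences — so permutation additivity stays exact — while
  keeping >70% of originals destabilizing, the class imbalance real tables
  show.
* `make_planted_task()` generates an antisymmetric regression target
  w*·(φ(to) − φ(from)) + γ·density(position)·(ψ(to) − ψ(from)) + ε, where φ
  is a fixed standardized amino-acid property embedding (hydropathy, volume,
  charge, polarity), ψ its volume channel, and density the standardized atom
  count within 8 Å of the position's Cα — a signal recoverable only through
  the microenvironment. Train and test positions are disjoint. A linear
  probe on φ-differences alone reaches Pearson ≈ 0.8 held-out; the
  microenvironment term is the headroom the model must explain to reach the
  0.9 acceptance bar.

What passing these tests shows: the architecture can extract a
position-dependent signal from atom geometry and combine it with amino-acid
embeddings under the antisymmetric decoder. What it does not show:
performance on real mutations — real microenvironments are irregular,
side-chain packing matters, and experimental ΔΔG noise is not Gaussian. The
published full-scale accuracies (e.g. >90% wild-type recovery) require
pretraining on millions of PDB microenvironments and are out of scope at
desk scale.

## Problem sizes and numerical choices

The test-suite and the acceptance script run a reduced configuration chosen
to exercise every code path in minutes on one CPU: token width 32, 2 blocks,
4 heads, 1-block head (`desk_config()`); the planted task uses 4 structures
× 24 residues, ~400 training records, 500 iterations of the frozen-backbone
recipe at lr 3e-3 and microenvironment radius 10 Å; toy pretraining uses 150
environments × 300 iterations. These sizes are the package's own desk-scale
presets; the full-scale defaults remain available through
`backbone_config()` and `train_config("paper")`.

Other pinned numerics: SASA uses the Shrake–Rupley algorithm with a
deterministic golden-spiral point set (960 points, probe 1.4 Å) — rotating
the point set with the structure reproduces values to 1e-6, independent
rotation agrees to ~1%; SASA feature values are divided by 100 inside the
model so both physical channels are O(1); microenvironments beyond 512
tokens truncate by ascending distance to the center; boundary atoms exactly
at a radius or cutoff are *included* (closed ball) so counts are
deterministic; softmax is computed in the max-shifted form and fully masked
keys receive probability zero; AUROC for the stabilizing class scores with
the negated prediction (more negative = more stabilizing), fixed so results
are reproducible across tools; both the 0 and −0.5 kcal/mol stabilizing
thresholds are supported and every report names the one it used.

## Open choices made here

The environment radius around the Cα is not fixed by the architecture; 16 Å
is the default (it comfortably contains the 8 Å pooling shell plus context)
and it is exposed everywhere as `radius`. The element-embedding width E = 20
is implemented as the atom-element embedding width; block count, head count
and MLP widths are sized to land near the ~1.2M-parameter budget (the exact
defaults give 1.08M). Whether the published decoder carries a bias is not
determinable from the reported near-zero self-mutation error; we default to
an exact zero because it is the cleaner inductive bias and make it a switch.
The regression head gets its own 2 attention blocks with fresh parameters,
separate from the pretrained backbone.

## Known limitations

No mmCIF input (PDB only); no mutant-structure generation, multi-point
mutations, or binding-affinity ΔΔG; no protonation or energy minimization;
the bundled charge table is a compact AMBER-style subset (backbone + Cβ) and
atoms outside it get charge 0 with a logged count — swap in a full
forcefield table via `charge_table` for production use; training is
single-threaded base R and intended for desk-scale experiments, not
PDB-scale pretraining.
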