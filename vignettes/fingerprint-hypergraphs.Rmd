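---
title: "Fingerprint-substructure hypergraphs for molecular property prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprint-substructure hypergraphs for molecular property prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Molecular property prediction is usually cast as message passing over the
atom-bond graph. `hypermol` instead passes messages one level up, between
*fingerprint substructures*: the circular atom environments that
extended-connectivity fingerprints (ECFPs) hash into a fixed-length bit
vector. Each molecule becomes a small graph whose nodes are its fingerprint
environments and whose edges ("positive hyperlinks") join any two
environments that share at least one atom. Because every environment is a
chemically meaningful fragment — a functional group, a ring neighbourhood —
the encoder reasons over fragments and their spatial overlap rather than
over individual atoms.

The pipeline is:

1. **Substructure extraction.** For every heavy atom $a$ and every radius
   $r = 0, \dots, R$ (default $R = 2$), the ball of radius $r$ around $a$ is
   a candidate environment $S_i = (V_i, E_i)$. A candidate is emitted only
   when the ball grew relative to radius $r - 1$, mirroring the standard
   ECFP suppression of duplicate environments; environments identical in
   both folded bit and atom set are deduplicated. Each environment carries a
   folded bit index: an iterative neighbourhood hash of the atom invariants
   (element, heavy-atom degree, formal charge, attached hydrogens,
   aromaticity) reduced modulo the fingerprint length $L$ (default 2048).
2. **Hypergraph generation.** All $\binom{|\mathcal{S}|}{2}$ unordered pairs
   are scanned; a pair with intersecting atom sets receives a positive
   hyperlink. Disjoint pairs (negative hyperlinks) are represented by the
   absence of an edge: the propagation rule below uses a standard binary
   adjacency, and a signed variant would require a different rule.
3. **Intra-Encoder.** Node features are one-hot over the *global* folded bit
   space: $X \in \{0,1\}^{|\mathcal{S}| \times L}$ with a single 1 per row.
   Using the global vocabulary (rather than a per-molecule identity matrix)
   is what lets one weight matrix serve every molecule.
4. **Inter-Encoder.** Either a GCN, layer-wise
   $H^{(k+1)} = \sigma\!\left(\tilde D^{-1/2} \tilde A \tilde D^{-1/2} H^{(k)} W^{(k)}\right)$
   with $\tilde A = A + I$, or a GIN, per node
   $h_v' = \mathrm{MLP}\!\left((1+\varepsilon) h_v + \sum_{u \in \mathcal{N}(v)} h_u\right)$
   with $\varepsilon = 0$ fixed and a two-layer perceptron
   (linear–rectifier–linear). The final propagation layer applies no
   activation before readout.
5. **Readout and head.** Sum pooling over nodes gives the molecule
   embedding; a sigmoid affine head gives per-task probabilities, trained
   with masked binary cross-entropy (missing labels contribute neither loss
   nor gradient), probabilities clamped to $[10^{-7}, 1-10^{-7}]$ before the
   logarithms.

## Training protocol

The protocol follows the common benchmark practice for scaffold-split
property prediction: Bemis–Murcko scaffold split 8:1:1, 100 epochs,
mini-batches of 32 (shuffled each epoch with the run seed, last partial
batch kept), rectifier activations, Adam, sigmoid + binary cross-entropy,
fingerprint length 2048 and radius 2, and three independently seeded runs
reported as mean ± standard deviation of the test ROC-AUC. Per-task AUC is
computed over non-missing labels by the Mann–Whitney rank identity (ties
0.5) and averaged unweighted across tasks; a task whose test slice contains
a single class is excluded from the mean and named in the log, never
imputed.

Choices the protocol leaves open, and what this package does:

* **Scaffold-split variant.** We use the deterministic largest-group-first
  greedy assignment with cumulative capacity cutoffs (groups sorted by
  descending size, ties broken lexicographically on the scaffold string),
  not random scaffold shuffling. Two calls on the same dataset give
  identical splits. Acyclic molecules share the single empty scaffold.
* **Scaffold definition.** Terminal atoms are pruned iteratively until only
  rings and linkers remain, and the canonical SMILES of the remainder is the
  group key. Exocyclic substituents, including double-bonded ones such as
  carbonyl oxygens, are removed — a slightly coarser grouping than the
  common toolkit convention, applied uniformly, so it can only merge groups,
  never split one inconsistently.
* **Depth, width, learning rate, model selection.** Not part of the stated
  protocol; defaults are 2 propagation layers, hidden width 128, Adam at
  1e-3, and best-validation-epoch checkpointing (a `"last_epoch"` mode is
  available for comparison). All are arguments of `hypermol()`.
* **Which environments become nodes.** Environments at *every* radius
  0..R are nodes (not only the final radius): the nested balls around one
  center are exactly what makes the hypergraph densely overlapping, and the
  iterative ECFP construction defines them all.
* **GIN epsilon.** Fixed at 0, non-learnable, the standard formulation.

## Numerical and implementation notes

* The one-hot input layer is never materialised at width $L$: with $X$
  one-hot, $X W$ is a row gather of $W$, and its gradient is a row
  scatter-add. Mini-batches are processed as one block-diagonal sparse
  adjacency with a per-node molecule index driving the readout; tests
  verify batched and per-molecule processing agree to 1e-6.
* Gradients (GCN and GIN, all layers, head, masked loss) are implemented
  analytically and verified against central finite differences at 1e-4 on
  tiny instances, at parameter scales away from the clamped-loss plateau.
* SMILES enter through OpenBabel canonicalisation, which fixes atom
  ordering and aromaticity perception; the environment hash is a 31-bit
  polynomial combine over the canonical atom invariants. Folding collisions
  are tolerated: distinct nodes may share a feature row, which at $L = 2048$
  is rare within one molecule and harmless to the encoder.
* Determinism: for a fixed dataset, seed list and single-threaded BLAS, the
  whole pipeline (split, initialisation, batch order, metrics) is
  reproducible bit for bit; the dataset generator restores the caller's RNG
  state.
* Degenerate inputs: a single-node hypergraph propagates through its
  self-loop only (the normalised adjacency is the identity); an all-missing
  label row contributes zero loss with zero weight; a molecule whose ball
  stops growing emits no further environments.

## What the synthetic generator does and does not show

`generate_molecules()` assembles guaranteed-valid SMILES from a fragment
grammar (alkyl chains, benzene/pyridine/cycloalkane/THF/naphthalene ring
templates, ether/amine/halide decorations) and attaches a task-specific
motif — by default a carboxylic acid, detectable at fingerprint radius 1 —
to a fixed-size random subset; labels are motif presence with optional
independent flip noise. The grammar contains none of the built-in motifs,
so the label signal is controlled exactly.

This emulates the *format* and the *learnability structure* of the
benchmark datasets (binary multilabel CSVs with missing values, scaffold
diversity, fragment-local signal), and it is what the acceptance checks
train on: n = 1000 molecules, noiseless labels, scaffold split 8:1:1, GCN
backbone, the full 100-epoch protocol over three seeds — sizes chosen so the
whole protocol runs comfortably on one CPU. It does not emulate real
structure-activity landscapes: real tasks are noisy, unbalanced, and carry
signal spread over interacting substructures, so a perfect ROC-AUC here
demonstrates that the pipeline can carry a fragment-level signal through
the hypergraph encoder, not that it will reach any particular score on
benchmark data.

## Limitations

* Hyperlinks are pairwise (shared-atom relations), not set-valued
  hyperedges; links are unweighted regardless of overlap size.
* Atom invariants exclude chirality; scaffolds are constitution-only.
* The environment hash is internally consistent but not bit-compatible
  with other toolkits' ECFP implementations; bit indices should not be
  compared across software.
* Training is plain dense/sparse linear algebra on CPU; it is sized for
  datasets of thousands of molecules, not hundreds of thousands.

## A worked example

```{r, eval = FALSE}
library(hypermol)

# a motif-labelled dataset: half the molecules carry a carboxylic acid
ds <- generate_molecules(1000, label_noise = 0, seed = 2024)

fit <- hypermol(ds, backbone = "gcn")   # full default protocol
summary(fit)
plot(fit)                               # validation curves per seed

# fingerprint sensitivity, as in the length/radius sweeps
sensitivity_sweep(ds, lengths = c(1024, 2048), radii = 2,
                  epochs = 20, seeds = 1L)
```
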