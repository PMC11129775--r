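---
title: "Tandem masked pre-training of SMILES and molecular graphs"
author: "tandemol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tandem masked pre-training of SMILES and molecular graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemol)
```

## Overview

`tandemol` implements masked-reconstruction self-supervised pre-training
jointly on two views of the same molecule — the SMILES token sequence and the
molecular graph — coupled through a shared Transformer fusion backbone and a
*coordinated, non-overlapping* masking strategy. This vignette documents the
method, the modeling assumptions, every parameter with its default, the
numerical choices, the synthetic-data semantics, and the limitations.

The central idea: the two views are redundant (every heavy atom appears once
in each), so if an atom is hidden in one view while its counterpart stays
visible in the other, reconstructing it rewards cross-modality information
flow rather than within-modality pattern completion. The package makes that
coupling explicit via an atom-index alignment between SMILES atom tokens and
graph nodes, and enforces mask disjointness exactly, per molecule, by
construction.

## Data representations

### SMILES tokenization (`tokenizeSmiles`, `buildVocabulary`)

The tokenizer is lossless: concatenating `tokens(ts)` reproduces the input
string byte-for-byte (a tested invariant). Token classes
(`classifyToken`) are `atom` (organic-subset symbols `B C N O P S F Cl Br I`,
aromatic `b c n o p s`, and any bracket atom `[...]` as a single token),
`bond`, `ring` (digits and `%nn`), `branch`, and `dot`. Atom tokens carry
strictly increasing atom indices in reading order. A `Vocabulary` is built
from a corpus with three reserved ids (`pad = 1`, `mask = 2`, `unk = 3`);
out-of-vocabulary tokens map to `unk`.

### Graph featurization (`featurizeGraph`)

A hand-written SMILES parser produces nodes in *the same reading order* as
the tokenizer's atom indices — this shared order is what makes alignment
trivial and exact. Node features are a fixed 28-column schema: element
one-hot over 11 elements plus "other", degree one-hot (0–5), formal charge,
aromatic flag, chirality one-hot (none/`@`/`@@`), attached-hydrogen count
one-hot (0–4). Implicit hydrogens follow standard organic-subset valence
rules. Edge features are 10 columns: bond-type one-hot
(single/double/triple/aromatic/other), conjugation flag, ring membership,
stereo one-hot. Ring membership is computed via `igraph::bridges` (an edge
is in a ring iff it is not a bridge). The test suite cross-checks atom
counts, element sequences, bond counts and ring atoms against
OpenBabel through `ChemmineR`/`ChemmineOB` as an independent oracle.

### Alignment (`alignAtoms`)

`alignAtoms(ts, g)` pairs token position and node index by shared atom
index and validates that the element symbols agree pairwise; mismatches are
errors, not warnings. The result is the substrate for mask sampling.

## Coordinated masking (`sampleMasks`)

For a molecule with `n` heavy atoms, with `maskedCount(r, n) =
max(1, round(r * n))`:

* the graph mask set `I_G` has size `maskedCount(rG, n)`, drawn uniformly;
* the SMILES mask set `I_S` has size `maskedCount(rS, n)` **as a fraction of
  all atoms**, not of the unmasked remainder, so `rS` means the same thing
  at every overlap setting;
* exactly `round(overlap * |I_S|)` members of `I_S` are drawn from `I_G`,
  the rest from its complement.

Defaults are `rG = 0.25`, `rS = 0.15`, `overlap = 0` — strictly disjoint
masks. The plan is a pure function of `(alignment, rG, rS, overlap, seed)`;
the sampler uses an isolated RNG stream and never perturbs the session RNG.
`auditMasks(plans)` recomputes pooled realized ratios and the realized
overlap `sum|I_S ∩ I_G| / sum|I_S|` from the stored index sets, which is how
both the test suite and `scripts/acceptance.R` verify the laws (overlap is
exactly 0 under the default; realized ratios approach 25% and 15% up to
`max(1, round(...))` rounding, which biases small molecules upward for the
graph mask and is why corpus means sit near, not at, the nominal ratios).

`applyMasks` produces the corrupted inputs: masked token positions are
replaced by the vocabulary's mask id; masked node rows are zeroed and
flagged so the graph encoder substitutes its learned mask embedding.

## Architecture

All matrices are row-major over positions with embedding width `d`
(`modelConfig`, defaults `d = 64`, `nHeads = 4`).

* **SMILES encoder** (`encodeSmiles`, `nLayersSmiles = 3`): learned token +
  positional embeddings, pre-layer-norm Transformer blocks (multi-head
  scaled-dot-product attention, GELU feed-forward with 4× expansion,
  residual connections). `selfAttention` exposes the primitive; its rows are
  convex combinations of the value rows (tested), and key masking excludes
  padding.
* **Graph encoder** (`encodeGraph`, `nLayersGraph = 3`): a communicative
  node–edge message-passing network. Hidden states live on directed edges;
  each inner step updates edge `u→v` from the sum of states on edges `w→u`
  with `w ≠ v` (boomerang exclusion), with a residual to the initial edge
  state; final node embeddings aggregate incoming edge states with the node
  projection. The construction is permutation-equivariant (tested).
* **Fusion backbone** (`fuseEmbeddings`, `nLayersBackbone = 3`): adds learned
  modality embeddings `A_S`, `A_G` to the respective rows, concatenates both
  sequences, and applies further Transformer blocks over the joint length
  `L + n`, so attention crosses modalities. With `nLayersBackbone = 0` the
  fusion reduces exactly to "inputs + modality embeddings" (tested identity).
* **SMILES decoder** (`decodeSmiles`): layer norm + linear LM head to
  vocabulary logits.
* **Graph decoder** (`decodeGraph`, `nLayersGraphDecoder = 1`): *re-masks*
  the masked node rows (replacing them with a learned decoder mask embedding,
  so information leaked into those rows by the backbone cannot shortcut the
  reconstruction — tested: perturbing a masked row leaves the output
  bit-identical), then GIN-style neighborhood aggregation and a linear
  projection back to the 28-column node feature space.

## Objectives and optimization

* `entropyLoss(logits, targets, maskedPositions)` — cross-entropy averaged
  over masked SMILES positions only (`l_en`).
* `sceLoss(xhat, x, maskedPositions, gamma = 2)` — scaled cosine error
  `mean((1 - cos(xhat_i, x_i))^gamma)` over masked node rows (`l_sce`).
  Identities at `gamma = 1`: perfect reconstruction gives 0, orthogonal rows
  1, anti-parallel rows 2 (tested).
* `totalLoss` — the unweighted sum `l_total = l_en + l_sce`.

Optimization uses AdamW (`lr = 1e-3`, `beta1 = 0.9`, `beta2 = 0.999`,
decoupled `weightDecay = 0.01` applied only to 2-D weight matrices, never to
biases, layer-norm parameters, or embeddings). Gradients come from a
hand-written tape-based reverse-mode autodiff (`R/autodiff.R`); every
operator is verified against central finite differences (step `1e-6`,
tolerance `1e-4`) in the test suite. No external numerical library is used
for the model itself.

## Pre-training loop (`pretrainConfig`, `runPretraining`)

Defaults: `iterations = 90000`, `batchSize = 8`, `gamma = 2`, `seed = 1`,
`logEvery = 10`, `checkpointEvery = 1000`. Each iteration samples a batch of
molecules and a fresh mask plan per molecule from a counter-based derived
seed (a pure function of the master seed, iteration, and position — all
derived seeds stay below 2^31), runs the forward pass per molecule,
accumulates gradients, and applies one AdamW update. Unusable corpus entries
(tokenization, featurization, or alignment failures; oversized sequences)
are excluded once at load with a message. Runs are bit-reproducible for a
given seed, and `resumeFrom =` a checkpoint continues the optimizer state
exactly (resume-equality is tested). Checkpoints are plain-text JSON.

## Downstream protocol (`scaffoldSplit`, `finetuneEncoder`)

`scaffoldKey` computes a Bemis–Murcko scaffold key: iteratively strip
degree-1 atoms not on a ring/linker path, then canonicalize the remaining
labeled graph with `igraph::canonical_permutation`. Acyclic molecules get an
`acyclic:`-prefixed whole-graph key, so distinct acyclic molecules form
distinct groups. `scaffoldSplit(df, fractions = c(0.8, 0.1, 0.1))` assigns
whole scaffold groups greedily by size so scaffolds never straddle splits;
a scaffold larger than the training budget triggers a warning.

`finetuneEncoder` attaches mean-pooling over node embeddings and a 2-layer
GELU head (`headWidth` defaults to `d`) to a pre-trained graph encoder
(`exportGraphEncoder(model)` or a checkpoint path), trains end-to-end with
AdamW and early stopping on the validation metric (`maxEpochs = 150`,
`patience = 20`), repeats over `seeds = 1:3`, and reports mean ± sd of test
ROC-AUC (%) for classification (`pROC`) or RMSE for regression.

## Synthetic generator semantics (`genSpec`, `generateCorpus`, `generateLabeled`)

The generator grows random valence-respecting molecules (rings, branches,
aromatic rings with optional `[nH]`, bracket atoms, charged counterions,
double/triple bonds) and writes them as SMILES directly; defaults
(`sizeRange = c(8, 40)`, all features on) are the study conditions used by
the tests and the acceptance script. Generation is deterministic in
`seed` and uses isolated RNG streams. Candidates failing internal validation
or falling below the minimum heavy-atom count are rejected and redrawn.

Labels (`generateLabeled`) are deliberately simple, *known* functions of the
structure: classification = "contains at least one ring" (balanced by
construction); regression = a fixed linear function of carbon count,
heteroatom count, and ring-atom count plus Gaussian noise
(`noiseSd = 0.1`), with the exact functional form recorded in the returned
`manifest` attribute. Consequently, synthetic results demonstrate that the
pipeline's machinery is correct — masks obey their laws, gradients flow
across modalities, training reduces loss, fine-tuning beats a label-shuffled
control on scaffold-disjoint splits — but say nothing about accuracy on real
chemical endpoints, where labels are not simple graph statistics.

## Problem sizes and numerical choices

The tested regime is small: corpora of 16–1000 molecules of 6–40 heavy
atoms, widths `d = 16–64`, 1–3 layers per component, hundreds of
iterations. Everything is dense `double` matrix algebra in base R; no
sparsity, no GPU. Softmax and layer norm use the standard max-subtraction
and epsilon (`1e-5`) stabilizations; the cosine in `sceLoss` guards
zero-norm rows with `eps = 1e-8`. Derived seeds are kept in `[0, 2^31)`.

## Limitations

* A CPU-bound reference implementation; orders of magnitude too slow for
  realistic pre-training corpora.
* The SMILES parser covers the organic subset plus bracket atoms, ring
  closures (including `%nn`), branches, dots, and directional bonds; it is
  not a complete SMILES dialect (no reaction SMILES, no isotope-dependent
  chemistry beyond storing the bracket token, no canonicalization).
* Masking operates on heavy atoms only; bond/ring/branch tokens are never
  masked.
* Synthetic labels are easy by design; downstream metrics on them saturate
  quickly and should not be read as benchmark numbers.
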