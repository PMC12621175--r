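---
title: "Designing nuclear-receptor ligands with a chemical language model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing nuclear-receptor ligands with a chemical language model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

`clmdesign` implements a transfer-learning pipeline for de novo molecular
design with a SMILES chemical language model (CLM), applied here to liver X
receptor (LXR) modulator discovery. The model is an autoregressive
next-token predictor: given the tokens emitted so far, it outputs a
categorical distribution over the next SMILES token, and a molecule is a
sequence `START, y_1, ..., y_t, END` with probability
`P(y) = prod_i P(y_i | y_1:i-1)`.

The network is the six-layer stack used at full scale: an input
BatchNormalization over the one-hot token features, three LSTM layers of
1024/512/256 units, a second BatchNormalization, and a Dense output of
vocabulary width (71 tokens at full scale, 8,444,003 parameters in total,
counting the non-trainable BatchNorm moving statistics). Training minimizes
categorical cross-entropy with Adam under teacher forcing; sequences are
right-padded and PAD positions are masked out of the loss.

The pipeline stages are:

1. **Corpus preparation** (`standardize()`, `build_corpus()`): isotopes and
   stereochemistry removed, the fragment with most heavy atoms kept (salt
   stripping), canonical SMILES emitted, duplicates removed, strings over
   140 characters excluded.
2. **Pretraining** (`pretrain()`): a general model of SMILES syntax learned
   from a large diverse corpus.
3. **Two-stage fine-tuning** (`fine_tune()`): first on a mid-size
   target-focused set with the first LSTM frozen, then on a small template
   set with the first and second LSTM frozen; 20 epochs, learning rate
   1e-4, reduce-on-plateau (factor 0.5, patience 3, floor 5e-5), dropout
   0.4 on the LSTM inputs, 10-fold randomized-SMILES augmentation in both
   stages. The stage list is configuration data, so a single-stage protocol
   is expressible for comparison.
4. **Epoch selection** (`select_epochs()`): at each fine-tuning epoch, 50
   representative molecules are decoded by beam search (cumulative
   log-probability scores, no length normalization) and compared to the
   template set by nearest-neighbour Tanimoto similarity on Morgan
   fingerprints (radius 2, 2048 bits); epochs whose aggregate falls in an
   acceptance band are kept for sampling.
5. **Sampling** (`temperature_sample()`): 2000 SMILES per selected epoch
   from the tempered softmax `q_i = exp(z_i/T) / sum_j exp(z_j/T)` with
   `T = 0.2`.
6. **Prioritization** (`frequency_rank()`, `similarity_prioritize()`,
   `dock_adapter()`): designs ranked by sampling frequency (an intrinsic
   quality proxy), by nearest-neighbour similarity to the template set
   (top 1000 kept), and optionally by the geometric mean of docking scores
   against both LXR isoform structures.
7. **Chemical-space reports** (`embed_tsne()`, `virtual_screen()`): t-SNE
   of Morgan fingerprints after truncated SVD to 50 dimensions with Jaccard
   distances and perplexity 30, and a spiked virtual-screening simulation
   ranked by consensus mean rank over the template queries.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `max_len` | 140 | longest admitted/generated SMILES (characters/tokens) |
| `learning_rate` | 1e-3 pretrain, 1e-4 fine-tune | Adam step size |
| `batch_size` | 8 | sequences per gradient step |
| `epochs` | 20 | fine-tuning epochs (one checkpoint each) |
| `plateau_factor/patience/min_lr` | 0.5 / 3 / 5e-5 | reduce-on-plateau |
| `dropout` | 0.4 | dropout on each LSTM layer's inputs |
| `augment_fold` | 10 | randomized SMILES per molecule during fine-tuning |
| `beam_width` | 50 | beam search width for epoch selection |
| `temperature` | 0.2 | softmax temperature for sampling |
| `n_samples` | 2000 | draws per selected epoch |
| `svd_dims`, `perplexity` | 50, 30 | chemical-space embedding |
| `retained_n` | 1000 | per-query virtual-screening list length |
| `autobox_size`, `exhaustiveness` | 8, 16 | docking grid and search effort |

## The synthetic study

Real corpora (365k ChEMBL molecules for pretraining, 252 BindingDB LXR
modulators, 12 hand-picked templates) are licensed downloads at a scale
unsuited to tests. `make_study()` generates a surrogate with the same
statistical skeleton: eight scaffold families (`default_families()`) built
from drug-like cores that echo LXR ligand chemotypes —
hexafluoropropanol aryl amides, diaryl piperazines, biaryl sulfone
benzylamines, oxyacetic acids, sulfonamides, ureas — each enumerated by
random substituent draws. Defaults: 2000 pretraining molecules over all
families, 120 fine-tuning-set-I molecules from three families, 10 set-II
templates sampled from set I across at least two families and excluded
from the pretraining corpus. All molecules are valid, canonical and under
140 characters by construction, so they pass `build_corpus()` unchanged,
and within-family nearest-neighbour similarity exceeds between-family
similarity — the structure both epoch selection and similarity
prioritization rely on.

What the generator does *not* emulate: bioactivity labels, assay noise,
the scale and chemotype breadth of ChEMBL/Enamine, and tail token
diversity (the synthetic vocabulary is ~25 tokens versus 71 at full
scale). Passing tests therefore demonstrate the correctness and the
qualitative behaviour of the pipeline machinery, not prospective design
performance on real targets.

## Numerical and design choices

* **Parameter counting** includes non-trainable BatchNorm moving
  statistics, because that convention reproduces the published full-scale
  total exactly; the closed forms are `4f` per BatchNorm, `4u(d+u+1)` per
  LSTM, `(d+1)v` for the Dense layer.
* **BatchNorm** uses batch statistics over all batch x time positions
  (PAD included) during training, momentum 0.99 and eps 1e-3, and moving
  statistics during generation — the convention of the Keras lineage this
  architecture comes from.
* **Plateau monitoring** uses the training loss (no validation split is
  part of the protocol); an epoch improves only when its loss is strictly
  below the best seen.
* **Layer freezing** is by recurrent-layer index in network order; the
  stage-1 protocol freezes LSTM 1, stage 2 freezes LSTM 1 and 2. Frozen
  tensors are conserved bit-identically (asserted in the tests).
* **Tokenization** is greedy character-level with `Cl`, `Br`, bracket
  atoms and `%nn` ring closures kept atomic; PAD is index 0, then START
  and END, then the sorted corpus tokens. The full-scale 71-token
  inventory is not published, so the vocabulary is always fitted to the
  corpus at hand and serialized with the checkpoints; `extra_tokens`
  reserves symbols (extra ring-closure digits, explicit bonds) that only
  appear in randomized augmentation variants.
* **Beam search** breaks score ties lexicographically by token indices,
  never expands PAD, and disallows END as the first token (no empty
  molecule). Hypotheses still active at `max_len` count as complete,
  truncated. Scores are raw cumulative log-probabilities.
* **Sampling** renormalizes the tempered softmax after zeroing PAD (and
  END at the first position); all randomness derives from the
  configuration seed, so a seed reproduces the identical multiset.
* **Epoch-selection aggregate** is the mean over valid beam designs of
  nearest-neighbour similarity; the comparison statistic is not pinned
  down at full scale, and the mean is the least surprising choice. The
  acceptance band is configurable (default 0.3–0.9: below, the model has
  not reached the target chemotypes; above, it is reproducing templates).
  An epoch with no valid beam design scores 0 with a warning.
* **Pooled sampling**: draws from the selected epochs are pooled before
  ranking (whether pooling happened per epoch or jointly at full scale is
  ambiguous; pooling is the default, per-epoch sampling remains available
  through the CLI).
* **Docking aggregation** defines the geometric mean of two same-sign
  affinities as `sign * sqrt(|a||b|)`; mixed signs are an error rather
  than a silent NaN. The engine itself (smina) is wrapped, not
  re-implemented; without it the docking columns stay empty and every
  other ranking is unaffected.
* **Jaccard after truncated SVD**: the stated distance is Jaccard but SVD
  scores are continuous, so the default binarizes the reduced vectors at
  0; a raw-fingerprint Jaccard mode is also provided. Members absent from
  a query's top-`retained_n` list are imputed rank `retained_n + 1` in the
  consensus, keeping mean ranks defined without unbounded penalties.
* **Dedup scope** is per corpus; cross-set deduplication is available in
  the CLI via standardization of concatenated corpora.
* **Desk-scale training recipe**: at full scale the base model sees 365k
  molecules, which buys robustness to the randomized-SMILES variants used
  during fine-tuning. A small synthetic corpus does not, so the package
  pretrains on the canonical corpus plus a few randomized variants per
  molecule (`augment_corpus()`, fold 2–4, or fully online re-randomization
  via `randomize_each_epoch`), keeping fine-tuning in-distribution.
  Without this, staged fine-tuning on augmented corpora degrades
  generation validity sharply.

## Problem sizes used in the tests

The test suite trains 64/48/32-unit models on a 600/60/8 synthetic study:
a canonical-corpus model (25 epochs) for the sampling-validity properties,
and a transfer chain (4-fold augmented pretraining for 20 epochs, then 12
fine-tuning epochs per stage, dropout 0.2) for the freezing and
template-shift properties. The pipeline smoke test uses 240/24/6 with a
48/32-unit model. The
acceptance script instantiates the full-scale architecture (it is cheap to
build; only training at that scale is out of desk scope).

## Known limitations

* Generation quality statements are made on the synthetic families;
  real-corpus behaviour (pretraining loss scales, epoch-selection bands)
  will differ.
* The docking adapter requires external binaries (smina, obabel) and
  prepared receptor structures; redocking fidelity can only be checked
  where those exist.
* The reference panel shipped for the novelty-band check covers the named
  reference ligands with fully specified structures (T0901317, GW3965);
  it is a partial, synthetic reconstruction of the fine-tuning tables,
  and nearest-neighbour similarities computed against it are lower bounds
  for designs whose closest template is not in the panel.
* Exact t-SNE is O(n^2) per iteration; it is intended for the desk-scale
  corpora used here (thousands of points at most).
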