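---
title: "Gapped pattern graphs and their convolutional embedding"
author: "gpgcn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gapped pattern graphs and their convolutional embedding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The representation

A DNA sequence of length $L$ is encoded as a *gapped pattern graph* (GPG).
For a k-mer size $k$ and a maximum gap length $d$:

* every one of the $4^k$ possible k-mers is a vertex, whose feature is the
  frequency of that k-mer among the $L-k+1$ windows of the sequence;
* every ordered k-mer pair $(s, t)$ is a directed edge, whose feature vector
  of length $d+1$ counts the occurrences of the spaced word $s\,x\,t$ for
  each spacer length $|x| = g \in \{0,\dots,d\}$. With $d = 0$ the edges
  reduce to exact 2k-mer concatenations (the plain pattern graph).

Gapped patterns (spaced seeds) tolerate substitutions and indels that break
exact k-mer matching, and a graph over *all* conceivable vertices and edges
gives every sequence a representation of identical shape with no arbitrary
serial ordering of k-mers. Counting is vectorized and linear in $L$ at fixed
$k$ and $d$ (the suite fits a log–log slope of runtime against
$L \in \{10^4, 10^5, 10^6\}$ and requires it to be $\approx 1$).

Two frequency conventions exist: absolute counts, and normalized counts in
which vertex entries are divided by $L-k+1$. Normalized counts are the
default. The edge denominator is stated nowhere for the gapped case, so the
package normalizes each gap-$g$ slice by its own window count
$\max(1, L-2k-g+1)$, the exact analogue of the vertex rule; normalization is
applied *before* any gap binning, so a coarse bin holds the sum of its
per-gap frequencies. For large $d$ the $d+1$ gap slices can be compressed by
`gap_binning()` into contiguous ranges; the identity binning is the default
for the small $d \le 2$ used throughout.

Ambiguity characters (N and the other IUPAC codes) are handled by skipping
every window — vertex or full $s\,x\,t$ span — that overlaps one, while
normalization denominators still use the full length. The sequence is
encoded strand-as-given; no reverse-complement canonicalization is applied.

## The network

Edge features take part in message passing by reifying every ordered pair
$(s, t)$ as a *pair vertex* connected to its two constituent k-mer vertices
(one when $s = t$). This bipartite topology depends only on $k$ and is
shared by all sequences; only the features differ. One convolution level
performs two steps with mean aggregation:

$$h_u^{l+1} = \sigma\!\left(B_1^l h_u^l + W_1^l\,
  \mathrm{mean}\{h_v^l : v \in N(u)\}\right)$$
$$h_v^{l+1} = \sigma\!\left(B_2^l h_v^l + W_2^l\,
  \mathrm{mean}\{h_u^{l+1} : u \in N(v)\}\right)$$

deliberately feeding the *updated* k-mer features into the pair update. The
mean over a self-pair's singleton neighborhood is the neighbor itself. The
suite pins both equations to a dense reference that materializes explicit
neighbor lists, and checks that permuting any neighbor list leaves the
output unchanged.

After $l$ levels the pair-vertex features, in lexicographic
$(\mathrm{index}(s), \mathrm{index}(t))$ order, form a $4^{2k} \times h$
array that a small 1-D convolutional head (two strided convolution layers,
global max-pool per channel concatenated with the flattened feature map, one
linear projection) reduces to the embedding. A fully connected softmax MLP
performs the task; per-sequence auxiliary features (e.g. protein
presence/absence vectors) are concatenated to the embedding at the first MLP
layer. The no-GCN ablation flattens the pair features directly into the MLP.

Choices the architecture description leaves open, fixed here as defaults and
all configurable: $\sigma = $ ReLU; head channels $h\to32\to8$ with kernel 8
and stride 4; embedding dimension 128; MLP hidden sizes (256, 64); weights
initialized uniformly in $(-1/\sqrt{\mathrm{fan~in}},
+1/\sqrt{\mathrm{fan~in}})$ under the run seed, biases zero. Max-pool ties
break toward the first position so reverse-mode gradients are well defined.

Two numerical points deserve mention:

* **Input scale.** Normalized frequencies are $O(4^{-k})$ and
  $O(4^{-2k})$ — at $k = 3$, pair features average $2.4\times10^{-4}$.
  Features therefore enter the first level as enrichment over the uniform
  background (vertex features $\times 4^k$, pair features
  $\times 4^{2k}$). This is a fixed diagonal re-parameterization of the
  first-layer weights: it changes no representable function, but keeps
  first-layer gradients at a scale Adam can use within a realistic epoch
  budget.
* **Training.** Mini-batch Adam at learning rate $10^{-4}$ minimizes the
  softmax cross-entropy with a probability floor of $10^{-12}$ inside the
  log. Batches are drawn with replacement with per-record weights
  $1/\mathrm{count}(\mathrm{class})$, so every class is seen equally often
  regardless of imbalance. Early stopping watches validation loss
  (patience 10 by default) and the weights of the best validation epoch are
  kept. A non-finite loss aborts with the offending epoch named.

Dataset splitting is stratified 80/10/10 by default (90/10/0 fits the
external-test design), with largest-remainder rounding so split sizes match
the ratios exactly. Grid search trains one model per cell, scores cells by
validation accuracy (macro-F1 by flag) and breaks ties toward the earlier
cell. With a window length $w > 0$ sequences are cut into non-overlapping
$w$-windows, each encoded as its own graph (a trailing partial window is
dropped; shorter sequences stay whole); record-level predictions and
embeddings average over a sequence's windows.

## Occlusion-based interpretation

The contribution of a set of gapped patterns is measured by zeroing their
pair-feature entries and recording the mean absolute change of the predicted
class probabilities over an evaluation set. Removal acts on the graph
features, not on the sequence string: the model consumes graphs, and
deleting pattern occurrences from the raw sequence would perturb every
overlapping window's features as a side effect. No renormalization follows a
removal, which keeps the occlusion local. Each motif — an IUPAC consensus
expanded exactly, not via PWM thresholds — maps to the set of all $s\,x\,t$
decompositions ($|x| \le d$) of its concrete realizations; its score is
compared against a baseline that removes the same *number* of uniformly
drawn patterns (10 repeats by default, seeded), and the motif is flagged
informative when its contribution strictly exceeds the baseline.

## What the simulator emulates

`generate_dataset()` produces labeled two-or-more-class sets: i.i.d.
background bases with configurable composition, per-class planted signatures
(concrete gapped patterns with fresh random spacers, or IUPAC motifs),
per-position SNP substitutions, per-position insertion/deletion noise, and
class-conditional Bernoulli auxiliary features that mimic protein
presence/absence encodings. Signatures are planted by overwriting
non-overlapping stretches, so sequence length carries no class signal.
Everything regenerates byte-identically from the master seed and the JSON
manifest.

The learnability study in the acceptance suite uses conditions chosen to
isolate exactly the property the representation claims: 100 sequences per
class of length 1000, class 1 planted with 10 copies of the gap-2 pattern
`ACG??TAC`, class 0 planted with 10 *unpaired* copies each of `ACG` and
`TAC`, and 1% SNP noise. Matching the marginal k-mer content between classes
removes all vertex-level signal, so only the gapped pairing separates the
classes — a model restricted to $d = 0$ must rely on weak junction
side-effects of planting. Ten copies per kilobase emulates a
signature-dense element (e.g. a repeated regulatory word at an integration
locus) while staying far from saturating the sequence. The study trains the
$d=2$ model, the $d=0$ model and the no-GCN ablation for up to 60 epochs
(patience 15, batch 32, learning rate $10^{-4}$) with reduced desk-scale
widths (hidden 8, head channels 16/8, embedding 32, one 32-unit MLP layer).

What these synthetic sets do *not* contain: phylogenetic correlation,
compositional heterogeneity (GC skew, repeats), realistic gene structure, or
any homology structure between train and test beyond i.i.d. sampling.
Passing tests therefore demonstrate that the implementation learns and
attributes planted gapped-pattern signal under noise — not that it
reproduces performance on real phage or bacterial genomes. In particular,
the advantage of graph convolution over the flattened-edge ablation is
reported in the literature for *novel, low-homology* sequences; on an
i.i.d. split with a cleanly separable planted signature the ablation can
match the full model, and the acceptance suite records whichever way that
comparison falls.

## Degenerate inputs and edge cases

Empty sequences or $L < k$ give all-zero graphs of full shape. Sequences of
only ambiguity codes likewise. Normalizing an already-normalized graph is an
error rather than a silent no-op, and per-gap normalization of an
already-binned graph is refused because the per-gap denominators are gone.
An empty pattern set removes nothing and scores zero. A motif shorter than
$2k$ contains no gapped pattern (shorter than $k$ is an error). Checkpoints
round-trip bit-exactly via `save_gpgcn()`/`load_gpgcn()`.

## Known limitations

* $k \le 8$ by construction (dense $4^{2k}$ pair space); practical use sits
  at $k \le 3$ in plain R.
* Single-threaded CPU training; the study sizes above run in minutes, but
  genome-scale corpora would need the batched GPU implementations of the
  ecosystem this package mirrors.
* Spectral directed-graph convolutions, motif discovery, and protein-scan
  feature extraction are out of scope; auxiliary features and motifs are
  consumed as precomputed tables/consensus strings.
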