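---
title: "Inferring Hi-C subcompartments from moderate-coverage data"
author: "hicsubcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring Hi-C subcompartments from moderate-coverage data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicsubcomp)
```

## The problem

Deeply sequenced Hi-C experiments show that, beyond the megabase-scale A/B
compartment split, the human genome segregates into five primary spatial
subcompartments — A1 and A2 (active, early-replicating) and B1, B2 and B3
(repressed, late-replicating) — visible as clustered patterns in the
*inter*-chromosomal contact matrix at 100 kb resolution. Calling these
subcompartments directly by clustering requires billions of read pairs;
typical Hi-C datasets (a few hundred million read pairs, under 100 million
of them inter-chromosomal) are far too sparse. This package infers
subcompartment annotations from such moderate-coverage data by first
*imputing* the dense inter-chromosomal contact structure with a denoising
autoencoder and then classifying each bin's low-dimensional contact
embedding with a multilayer perceptron (MLP).

## The model

The inter-chromosomal matrix places odd-numbered autosomes on the rows and
even-numbered autosomes on the columns. Because the matrix is not symmetric,
two independent model pairs are trained: one annotates the rows (odd
parity), the other the columns via the transposed matrix (even parity). A
bin is only ever annotated by its own parity's models.

**Contact probabilities.** Raw counts are mapped elementwise to
\(P_{ij} = \exp(-1/C_{ij})\), with \(P_{ij} = 0\) when \(C_{ij} = 0\) (the
analytic limit; no pseudocount, so sparsity is preserved). The transform is
strictly increasing, bounded in \([0, 1)\), and compresses extreme counts so
that both tails converge to 0 or 1 — this is what allows binary
cross-entropy (BCE) optimisation and protects the networks from outlier
signals. Raw counts are the expected input; pre-normalised (e.g. balanced)
matrices are accepted unchanged, since the transform is monotone the
downstream machinery is insensitive to that choice.

**Denoising autoencoder.** Nine dense layers of widths
\(N_{\mathrm{loci}}, 1024, 512, 256, 128, 256, 512, 1024,
N_{\mathrm{loci}}\), where \(N_{\mathrm{loci}}\) is the number of bins of
the opposite parity. Hidden layers are ReLU, the 128-unit latent layer is
linear (maximising the usable encoding space), and the output layer is
sigmoid to match the probability range. The hidden layers at the 1024- and
256-unit positions — on both the encoder and decoder sides — are followed by
25% dropout during training. Training minimises BCE between the
reconstruction of a *downsampled* probability row and the corresponding
dense row (an MSE mode is provided and behaves similarly), using mini-batch
backpropagation with RMSProp (decay 0.9, epsilon 1e-7), learning rate
0.001, batch size 32, 25 epochs. The odd model trains on rows of chr1, 3,
5, 7 (about half of the odd-parity bins); the even model on chr2, 4, 6, 8,
10 after transposing.

**Classifier.** The 128-dimensional latents are squashed through a sigmoid,
passed through ReLU hidden layers of widths 64 and 16 (a 32-unit variant is
available; both train fine) with 25% dropout, and a 5-unit softmax head.
Training minimises categorical cross-entropy with the same optimiser
settings. Before training, the set is *balanced*: for each class, `n`
synthetic latents are drawn as \(r = x + (y - x)\,u\), \(u \sim U(0,1)\),
from random same-class pairs, with `n` exceeding the largest class count, so
each subcompartment contributes exactly `n` of the \(5n\) training rows.

**Downsampling.** Coverage titration uses per-cell binomial thinning
(`keep_rate` of the reads kept), which has the same marginal distribution as
subsampling the original read pairs; read-level identities are not needed.

## Conservation across cell types

Given annotations of the same bins in \(N\) cell types, each bin gets label
fractions \(p_c\), the annotation entropy \(S = \sum_c -p_c \log p_c\)
(natural log; \(0\log 0 = 0\)), and per-label information content
\(IC_c = |p_c \log(p_c / q_c)|\) against a uniform background
\(q_c = 0.2\). Because annotations are discrete, the entropy takes finitely
many values: for \(N = 9\) there are exactly 23 count multisets, hence 23
entropy values. Multisets in which no label reaches a strict majority
(fewer than 5 of 9 cell types) — 11 of the 23 — merge into one
non-conserved (NC) state; the remaining 12 are numbered 1–12 by ascending
entropy, state 1 being perfectly conserved bins. State identity depends
only on the entropy *ordering*, so it is invariant to the logarithm base
(the tests verify this with log2). Bins with any missing annotation are
excluded from state assignment and flagged instead.

## The planted-truth simulator

`planted_model()` + `simulate_hic()` generate an inter-chromosomal count
matrix with known subcompartment structure: each bin carries one of the
five labels, and \(C_{ij} \sim \mathrm{Poisson}(d\, R_{\ell_i \ell_j} / Z)\)
with a symmetric positive 5×5 propensity matrix \(R\), normalised so the
expected total equals the depth \(d\). The default \(R\) encodes the
qualitative biology the method relies on — strong A1–A1/A2–A2 affinity,
strong B3–B3, B1 intermediate, weak A–B cross terms — without claiming real
contact frequencies. Labels are laid out in contiguous runs (geometric
lengths, minimum 3 bins ≈ 300 kb, mean 700 kb) on pseudo-chromosomes with
decreasing sizes, so that chr1/3/5/7 hold roughly half the odd-parity bins
(mirroring the real training split) and boundary analyses have genuine
domain boundaries to find. The default study conditions are 400 × 400 bins
and depth 2×10⁶ (a mean of 12.5 counts per cell; 10% downsampling then
leaves ~1.25).

What the simulator does *not* emulate: distance-dependence within
chromosomes (irrelevant inter-chromosomally), copy-number and structural
variation, mappability gradients, karyotype, or matrix-balancing artefacts.
Passing the recovery tests therefore demonstrates that the implementation
learns block-structured Poisson contact patterns at realistic sparsity — not
that real-genome accuracies are reproduced.

## Numerical and design choices

* **Weight initialisation** (unspecified by the underlying method):
  seeded uniform fan-in scaling at the He variance-preserving scale,
  \(U(\pm\sqrt{6/n_{\mathrm{in}}})\). The variance-preserving scale matters
  at desk scale: with a conservative \(1/\sqrt{n_{\mathrm{in}}}\) scale,
  activations shrink ~6× per ReLU layer and the latents collapse towards
  zero.
* **Latent standardisation.** The classifier stores per-dimension mean and
  standard deviation of its (balanced) training latents and standardises
  inputs before the sigmoid squashing. The latent scale is arbitrary (the
  latent layer is linear), and without standardisation small-scale latents
  land in the sigmoid's flat centre where class differences are compressed
  ~4-fold. At large data scales where latents are O(1) this is a benign
  affine reparameterisation; at desk scale it is essential.
* **Balancing default** `n = max(2 × largest class, 500)`. The balancing
  rule only requires `n` to exceed the largest class; on small fixtures the
  minimal choice would give the classifier only a handful of gradient
  updates per epoch, so the default guarantees a reasonable optimisation
  budget. At real-data scale (thousands of training bins) the two rules
  nearly coincide.
* **RMSProp constants** beyond the learning rate: decay 0.9, epsilon 1e-7.
* **Eq-8 at zero counts** is defined as probability 0 (analytic limit), not
  a pseudocount.
* **Tie-breaks**: exact argmax ties in classification resolve to the first
  label in A1, A2, B1, B2, B3 order.
* **Zero-marginal bins** (centromeric/unmappable): excluded from training,
  annotated NA.
* **B2/B3 are never merged** in conservation-state computation (merging is
  purely a display convention for replication-timing figures elsewhere).
* **PR curves** use step-wise interpolation, never linear, to avoid
  optimistic areas under the precision–recall curve.
* **Boundary profiles** drop boundaries whose 400 kb window is truncated by
  a chromosome end or spans NA bins; enrichment fold changes exclude
  terminal short bins.

## Problem sizes used by the test suite

Unit tests run on 60 × 60-bin fixtures with proportionally small network
interiors (32–16–8), which exercise every code path in seconds. The
recovery experiments use the default 400 × 400 fixture with the full
1024–512–256–128 architecture: ten seeds of the complete
train-and-annotate pipeline for label recovery (held-out accuracy ≥ 0.9)
and the imputation-improvement check, plus a five-point coverage titration
(40% down to 2% of reads). These sizes were chosen so the full suite
completes on a single CPU in well under half an hour while still training
the genuine architecture.

## Known limitations

* Desk-scale training budgets are necessarily small: an "epoch" over ~200
  fixture rows is ~30× fewer gradient updates than an epoch over a real
  genome's training split, so fixture accuracies carry more seed-to-seed
  variance than the method exhibits at scale.
* The two coverage-specific model variants used in cross-cell-type work
  (10%- and 5%-trained) are supported by fitting at different `keep_rate`s;
  selecting between them by a read-count threshold is left to the caller
  (the default boundary used in practice is ~45 million inter-chromosomal
  pairs).
* `.hic`/cooler binaries are not parsed natively; export contacts to
  triplet text with the standard extractors first.
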