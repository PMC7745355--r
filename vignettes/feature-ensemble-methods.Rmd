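---
title: "Feature ensemble learning for lncRNA prediction: models and design choices"
author: "lncEnsemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature ensemble learning for lncRNA prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncEnsemble)
```

## The problem

Distinguishing long non-coding RNAs (lncRNAs) from protein-coding
transcripts (PCTs) from sequence alone is a binary classification task.
The discriminating structure is well understood biologically: a coding
transcript carries a long open reading frame whose codon and hexamer
usage is strongly biased, and whose translated peptide has
characteristic physicochemical properties; a lncRNA does not. The
package encodes each transcript into six complementary feature families
and then *fuses* the families with one of two ensemble strategies — an
iterative stacking of per-family random forests (IEL) or an
attention-weighted embedding network (ANEL).

All sequences live in a single internal DNA alphabet: input U is mapped
to T so that every k-mer table, codon table and property table is
written once. Ambiguity codes are rejected rather than silently
dropped, because k-mer counting over ambiguous bases is undefined here;
a `dropAmbiguous` flag downgrades the rejection to a logged skip.

## The six feature families

1. **Transcript-specified (38 dims).** ORF length (first complete ORF),
   ORF coverage (longest ORF / transcript length), ORF integrity
   (longest ORF has both start and stop), Fickett TESTCODE score,
   hexamer log-ratio score, and the translated peptide's isoelectric
   point, GRAVY hydropathy and instability index, plus the
   30-dimensional composition/transition/distribution (CTD) descriptor.
   Conventions worth stating: the *first* ORF is the complete ORF with
   the smallest start; the *longest* ORF admits incomplete spans (ATG
   with no in-frame stop), which therefore get integrity 0; translation
   keeps the initial Met and drops the stop; the pI is solved by
   bisection of the Henderson–Hasselbalch net charge under the
   Bjellqvist/Expasy pKa set to |charge| < 1e-4; CTD distribution cells
   use the ceil(q·count)-th occurrence for q in {25, 50, 75, 100}% with
   the first occurrence as the 0% point.
2. **Spectrum profile (1364 dims).** k-mer frequencies for k = 1..5,
   each count divided by the number of windows L − k + 1, so each per-k
   block sums to one.
3. **Reverse-complement k-mer profile.** Spectrum counts folded onto
   canonical representatives, the lexicographically smaller of each
   {x, revcomp(x)} pair. Per-k dimensions are 2 / 10 / 32 / 136 / 512.
   *Dimension note:* published tabulations of this descriptor sometimes
   list 528 for k = 5; that figure is unreachable under the canonical
   folding (an odd k admits no palindromic k-mers, so the count is
   exactly 4^5/2 = 512), and the package follows the definition.
4. **Mismatch profile (1344 dims).** For each pattern, the number of
   windows within Hamming distance m (default pairs (3,1), (4,1),
   (5,1)), normalized by the window count. Windows are shared among
   patterns, so rows are not probability-normalized; m = 0 reduces
   exactly to the spectrum profile.
5. **Pseudo nucleotide composition (310 dims).** Five Chou-type
   variants. Parallel-correlation variants (PseDNC, PC-PseDNC,
   PC-PseTNC) add one θ per correlation tier, the mean squared
   difference of standardized property values; series-correlation
   variants (SC-PseDNC, SC-PseTNC) add one τ per (property, tier), the
   mean *product* of standardized values. Defaults (λ, w) = (7, 0.5),
   (7, 0.7), (6, 0.7), (7, 0.1), (6, 0.1). Every vector is normalized
   to total 1 by the shared denominator 1 + wΣθ; parallel variants are
   additionally nonnegative, series variants need not be (products can
   be negative — this is inherent to the series-correlation
   definition).
6. **Auto-cross covariance (280 dims).** The sequence is expanded into
   overlapping dinucleotides (DACC, six standardized B-DNA base-step
   parameters) or trinucleotides (TACC, two composite flexibility
   tracks) and lagged auto/cross covariances are computed for lags
   1..7, giving 36·lag + 4·lag dimensions.

The dinucleotide property table ships in-source (twist after Gorin,
Zhurkin & Olson 1995, remaining steps literature B-DNA averages) and is
standardized per row before any use, so only the relative pattern of a
property across oligomers matters. The trinucleotide tracks are
composed from the step parameters (per-trinucleotide mean and
step-to-step change of each property), which supplies the twelve
standardized tracks the series-correlation trinucleotide composition
requires and the two tracks the trinucleotide covariance uses. These
tracks are structural composites assembled for this package, not
transcriptions of a single published twelve-property table; every test
and oracle evaluates the covariance and correlation *formulas* against
the same packaged table, which is the property being asserted.

The Fickett lookup tables are the published TESTCODE position/content
probabilities and weights; the hexamer reference table is always
rebuilt from the training partition at hand (never from test data), so
its provenance is explicit and leakage-free.

## Feature selection

Each family is reduced in two steps: a one-way ANOVA F ranking (the
classic between/within variance ratio; constant columns get F = 0,
perfectly separating columns F = ∞), then a greedy mRMR ordering of the
top-500 candidates under the MID criterion — maximize mutual
information with the label minus mean mutual information with the
already chosen columns — with MI estimated by equal-frequency 10-bin
discretization and the plug-in formula. Subset sizes from the grid
{10, 20, 50, 100, 200, 500} are scored by a small validation random
forest and the best validation AUC wins, ties to the smaller size. The
pool size, grid, bin count and forest size are explicit configuration
(`selectionControl()`), since "optimal subset" is otherwise
underdetermined; selection is always fit inside the current training
fold.

## IEL: iterative stacked ensemble

One probability random forest (500 trees, seeded, single-threaded for
reproducibility) is trained per family on its selected columns. Round
t of the iteration trains a stacking forest on the scores of all
current predictors — the six bases plus the t − 1 previous stacks, so
the round-t input has exactly 6 + (t − 1) dimensions — and then adds
itself to the predictor set. Two details matter:

* Stacking inputs on the training partition are **out-of-fold**: each
  score column is produced by internal stratified 5-fold refits, so no
  stack ever sees an in-fold prediction of its own training row.
  Without this the stack saturates immediately on leaked in-sample
  scores.
* Early stopping watches the validation AUC: fewer than `tol = 1e-3`
  improvement for two consecutive rounds stops the chain, with
  `maxRounds = 18` as the hard cap. On the synthetic benchmark the
  chain typically converges within a handful of rounds.

Prediction applies the bases and then each chain member in order; the
last chain member's output is the model score, thresholded at 0.5 for
SN/SP/ACC.

## ANEL: attention network ensemble

Each family's (selected, column-standardized) features are embedded by
an affine layer into a shared dimension d = 128, passed through
dropout (p = 0.5), and fused by a shared attention scorer:

$$h_i = \mathrm{ReLU}(W_w f_i + b_w),\qquad
\alpha_i = \frac{\exp(h_i^\top h_w)}{\sum_i \exp(h_i^\top h_w)},\qquad
F_{att} = \sum_i \alpha_i f_i,$$

followed by a 128→64→2 ReLU MLP head with a 2-class softmax and
cross-entropy loss. The softmax over the six families is numerically
stabilized by subtracting the per-sample max logit; α is nonnegative
and sums to one per sample, so F_att is a convex combination of the six
embeddings. W_w, b_w and h_w are shared across families (the equations
index only the embedding by family); the embedders are per-family.
Training uses Adam (lr 5e-3, batch 32, 23 epochs), Kaiming-style
uniform initialization, all randomness derived from one seed; the
parameters with the best validation AUC are restored at the end, and
optional early stopping on validation loss is available. The network is
implemented directly in matrix algebra with analytic backpropagation —
the gradient is verified against central finite differences in the test
suite — which keeps the model fully inspectable: `attentionWeights()`
exposes the per-sample α for interpretability.

Whether the attention network should consume raw blocks or the
mRMR-selected subsets is genuinely open; the package defaults to the
selected subsets when a selection is supplied and raw blocks otherwise
(`selections = NULL`), switchable per call.

## Evaluation protocol

`crossValidate()` runs stratified 5-fold CV; within each fold the
remaining four fifths are split 80/20 (stratified, seeded) into
training and validation. The hexamer table, standardization statistics,
feature selection and all model fitting happen strictly inside the
fold's training partition; validation drives subset sizes, early
stopping and checkpointing; SN, SP, ACC (threshold 0.5) and rank-based
AUC (Mann–Whitney, ties 0.5) are computed on the held-out fold and
aggregated as mean ± sd. Stratification is a deliberate choice for
stability at desk scale; the splits are reproducible from the seed.

## The synthetic generator

`generateDataset()` emulates the contrast the classifier exploits,
without downloads. Negatives are UTR + ATG + codon body + stop + UTR,
with codons drawn from a fixed human-like usage table mixed with the
uniform distribution by `codonBiasStrength`, and the ORF covering
`orfFracNeg` of the transcript. Positives are the *same* construction
passed through an Altschul–Erickson dinucleotide-preserving shuffle, so
base and dinucleotide composition match between classes exactly and
only ORF/codon structure separates them — a classifier cannot pass by
reading GC content. Defaults: 300 + 300 transcripts of 200–1000 nt,
`orfFracNeg = 0.7`, `codonBiasStrength = 0.8`, a realistic contrast for
a desk-scale benchmark. Setting both contrast knobs to zero makes the
classes exchangeable (the null configuration), which the tests use as a
type-I check: cross-validated AUC must hover at 0.5.

What the generator does *not* emulate: splicing and isoform structure,
real length and expression distributions, sequencing error, and the
redundancy structure of curated databases. Passing the synthetic
benchmark therefore demonstrates that the pipeline's machinery works
and that its inductive biases point the right way — not that the
reported numbers transfer to GENCODE-scale data.

## Numerical choices and degenerate inputs

* Lexicographic A &lt; C &lt; G &lt; T ordering everywhere; canonical
  reverse-complement representative is the lexicographic minimum.
* Count profiles are normalized by windows (L − k + 1), not by L.
* Sequences shorter than a k, λ or lag requirement either produce a
  zero block (spectrum) or raise a named error (pseudo composition,
  covariance) — never a silent NA.
* A transcript with no ORF contributes zeros for all ORF/peptide
  features and falls back to whole-sequence hexamer windows.
* Random forests run with `num.threads = 1` and explicit seeds:
  identical inputs and seed give identical models.
* Ties in rankings and size grids always break toward the smaller
  index/size, making selection deterministic.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at
n = 600 (the default generator output) with the default configuration,
and the property tests use the smallest sizes at which the checked
estimator is stable (e.g. 150 per class for the codon-bias/hexamer-gap
monotonicity, 1000 simulated columns for the ANOVA null expectation).
These sizes are the package's chosen benchmark conditions.

## Known limitations

* The trinucleotide property tracks are composites derived from
  dinucleotide step parameters (see above), adequate for the covariance
  formulas' contracts but not a substitute for curated trinucleotide
  scales.
* The mismatch profile materializes a 4^k × 4^k neighbor matrix per
  (k, m); fine through k = 5, not intended for much longer k.
* The attention network is a compact two-layer design; it is not a
  drop-in for GPU-scale training, and its absolute losses on large
  corpora are out of scope here.
* Random-forest stacking ranks well but its probabilities are not
  calibrated: at small sample sizes the IEL score distribution can sit
  asymmetrically around the fixed 0.5 decision threshold, trading
  specificity for sensitivity while AUC — the primary, threshold-free
  metric — is unaffected. One contributing mechanism is that the
  hexamer reference table, rebuilt from the training partition (the
  standard practice, and the only leakage-free option), scores its own
  training sequences optimistically when the partition is small — each
  sequence's hexamers are part of the table — so downstream forests
  over-trust the feature until the table is estimated from a few
  hundred sequences. Users who need calibrated SN/SP at small n should
  recalibrate the final score (e.g. Platt scaling on the validation
  part) before thresholding.
* Redundancy removal (CD-HIT-style clustering) is upstream of this
  package: feed it deduplicated transcripts.
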