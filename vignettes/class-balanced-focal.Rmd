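---
title: "Class-balanced positive/negative weighting for imbalanced multilabel classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-balanced positive/negative weighting for imbalanced multilabel classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbfocal)
```

## The problem

Multilabel classifiers for chest-radiograph findings face severe class
imbalance: over the canonical 112,120-image corpus the rarest finding
(hernia) appears in 227 images (prevalence 0.2%) while the commonest
(infiltration) appears in 19,894 (17.7%). With one sigmoid node per finding
and an unweighted binary cross-entropy loss, the gradient is dominated by
the plentiful negatives, and rare-class nodes barely learn. `cbfocal`
implements a weighting scheme that addresses this by combining three ideas:

1. **Effective number of samples.** The information contributed by $n_k$
   positives of class $k$ saturates; it is modelled by the geometric sum
   $(1-\beta^{n_k})/(1-\beta)$, whose reciprocal (scaled by $1-\beta$) gives
   the raw class weight
   $$\alpha_k(\beta) = \frac{1-\beta}{1-\beta^{n_k}},
   \qquad \beta \in [0, 1).$$
   $\beta = 0$ gives uniform weights; $\beta \to 1$ recovers
   inverse-frequency weighting $\alpha_k \to 1/n_k$. A natural choice ties
   $\beta$ to the training-set size $N$ via $\beta = (N-1)/N$.

2. **A positive/negative split.** After normalizing the $\alpha_k$ (below),
   the positive-pattern weight of class $k$ is
   $\omega_{k+} = \tilde\alpha_k$ and the negative-pattern weight is the
   complement $\omega_{k-} = 1-\omega_{k+}$. A node's loss term is
   multiplied by $\omega_{k+}$ when its ground-truth label is 1 and by
   $\omega_{k-}$ when it is 0.

3. **The focal term.** The per-node loss is
   $\omega \, \alpha \, (1-p_t)^\gamma \, (-\log p_t)$ with
   $p_t = p$ for a positive label and $1-p$ for a negative one, so
   well-classified nodes are down-weighted; $\gamma = 0$, $\alpha = 1$
   recovers weighted cross entropy. Defaults are $\alpha = 0.5$,
   $\gamma = 1$.

All of this is computed on the *training split*'s per-class counts, because
that is where the loss operates.

## Normalization: two readings, one default

With $N(\beta) = \sum_k \alpha_k(\beta)$ and $C$ classes, the package
offers two normalizations:

- **`paper-c`** (default): $\tilde\alpha_k = C\,\alpha_k/N(\beta)$, so the
  *mean* weight is one. For rare classes this gives $\tilde\alpha_k > 1$,
  which drives $\omega_{k-} = 1-\tilde\alpha_k$ negative. A negative loss
  weight is not meaningful, so such $\omega_{k-}$ are floored (default 0),
  flagged in the weight table, and warned about. A floored class receives
  no gradient from its negative labels.
- **`sum-to-one`**: $\tilde\alpha_k = \alpha_k/N(\beta)$, so all
  $\tilde\alpha_k \in (0,1)$ and both $\omega_{k+}$ and $\omega_{k-}$ stay
  strictly positive for every class.

The `paper-c` form follows the published formula literally and is the
package default; the `sum-to-one` mode exists because the flooring
consequence of `paper-c` — a rare class whose negatives are silently
ignored — is drastic enough that the scaled variant is worth having as a
first-class option. On the 14-class count table with $\beta = 0.9998$,
three classes cross the $\tilde\alpha_k > 1$ line — hernia emphatically
(6.45), pneumonia and fibrosis marginally; at smaller class counts and
smaller $C$, more classes cross it.

```{r weights-example}
counts <- read_class_counts(cxr14_counts_path())
w <- class_weights(counts, beta = 0.9998) # warns: 3 classes floored
dplyr::filter(tidy(w), class %in% c("Hernia", "Infiltration"))
```

## Prevalence-aware evaluation

AUROC has a fixed 0.5 chance level, but the area under the
precision-recall curve does not: a random scorer achieves the positive
prevalence
$$\mathrm{AUPRC}_{\mathrm{baseline}} = \frac{P}{P+N},$$
0.50 for balanced classes, about 0.09 when negatives are tenfold, 0.0020
for the 227-positive class. `evaluate_scores()` therefore reports, per
class, AUROC, average precision, this baseline *from the evaluation set's
own label distribution*, and the lift (AP minus baseline). Average
precision uses the step estimator (precision summed over recall
increments), not trapezoidal interpolation, which is known to be
optimistic for PR curves. Reported baseline columns follow a truncation
convention: digits beyond the fourth decimal are dropped, not rounded
(2776/112120 = 0.024759 prints as 0.0247); macro averages are taken over
full-precision per-class values and truncated last, which is the order
that reproduces the published 14-class average of 0.0517. Macro averages
are unweighted means over classes that have at least one positive and one
negative; degenerate classes are flagged `NA` and excluded.

## The synthetic test bed

Real radiographs are out of scope; the generator instead reproduces the
*statistical* difficulty — skewed independent Bernoulli labels (defaults:
five classes at prevalences 0.5%, 2%, 8%, 15% and 30%, spanning the
rare-to-common range of the motivating corpus) — on trivially simple
images: each class owns a fixed geometric template (disks, squares, rings
on a 3×3 anchor grid) stamped onto i.i.d. Gaussian noise. Defaults are
64-pixel images, signal amplitude 1 and noise SD 4, i.e. a per-pixel SNR
of 0.25, so no single pixel separates the classes and a classifier must
integrate over a template's support. Fixed templates make the Bayes-optimal
scorer an explicit matched filter (`bayes_scores()`), giving metric tests a
known ceiling and the benchmark a sanity bound.

What this generator deliberately does *not* model: label co-occurrence
structure (the weighting uses only marginal counts, so correlated labels
add no test power), anatomical content, and acquisition artefacts.
Passing tests on this bed validate the weighting/loss/metric machinery
and the training protocol's mechanics — not clinical performance.

## The reference backbone and the two-stage protocol

No deep-learning framework is assumed; the package ships a deliberately
small reference classifier adequate for desk-scale experiments: a fixed
3×3 filter bank (blur, Sobel-x, Sobel-y, Laplacian), adaptive average
pooling of each channel to an 8×8 grid, one 16-unit hidden layer (swish by
default) and a C-node sigmoid head, trained by hand-written
backpropagation through the exact loss gradients of `batch_loss_grad()`.
Only the dense layers are learned, so parameters transfer unchanged
between input resolutions — the property progressive resizing relies on.
The edge channels follow the derivative-of-Gaussian convention (gradients
are taken on a blurred image): without this, the finest-scale noise that
exists only at the higher resolution leaks into the edge features,
pooled features decorrelate between stages, and a stage-2 warm start
*loses* accuracy on arrival. Optimizers: Adam, and a rectified-Adam +
Lookahead combination ("ranger"); default learning rate 1e-2, appropriate
for the small dense head trained from scratch (the much smaller rates
common in transfer learning apply to fine-tuning large pretrained
backbones, not here).

`run_two_stage()` trains at a base resolution, then doubles the input
size, halves the batch size and warm-starts from the best stage-1
checkpoint, selecting every stage's best epoch by validation macro AUROC
with early stopping. The warm-started stage also drops the learning rate
fourfold: it is a fine-tuning pass, and restarting a fresh Adam state at
the full rate can wreck the inherited checkpoint before the first
validation snapshot. A third stage is supported but off by default; in
the motivating work it brought no further gain.

## The desk-scale benchmark

`imbalance_benchmark()` is the package's end-to-end experiment: per seed,
one n = 2000 dataset (defaults above) split 80/20 into train/validation,
both arms — unweighted BCE and the class-balanced weighted focal loss
(β = (N−1)/N from the training-split size, focal α = 0.5, γ = 1) —
trained through the 32→64, batch 32→16 two-stage protocol (up to 20
epochs per stage, patience 6), then scored on an independent 6000-sample
evaluation set. The large fresh evaluation set exists because a 400-image
validation split contains only a couple of rare-class positives, and
average precision on two positives is noise, not measurement. Both arms
share one optimizer (Adam) so the comparison isolates the loss; the
ranger optimizer remains available and is the default suggestion for
weighted-focal production runs. The stage-1 versus stage-2 comparison is
also made on the test set: the maximum of a noisy validation metric over
a stage's epochs systematically flatters the stage that visits more
distinct models (a from-scratch stage), so best-validation scores of the
two stages are not comparable. Problem sizes were chosen so a full
paired 5-seed comparison is a desk-job for a single CPU.

`summarize_benchmark()` reports the orderings without presupposing them:
how often the weighted arm matches or beats BCE on macro AU-PRC, how
often stage 2 matches or beats stage 1, and the mean paired difference.
A reweighting scheme is not guaranteed to win at this scale — a shallow
backbone fed abundant supervision can sit near its own ceiling, where
down-weighting common-class positives costs more macro AP than
up-weighting an intrinsically noise-bound rare class recovers — so the
benchmark should be read as a measurement instrument, not a
demonstration.

## Numerical choices

- $\alpha_k(\beta)$ is evaluated as `(1-beta) / (-expm1(n * log1p(beta-1)))`;
  the naive `beta^n` underflows for the large counts and near-one betas in
  routine use. Tests pin it to an independent geometric-series route at
  1e-10 relative tolerance.
- Probabilities are clipped to `[1e-7, 1-1e-7]` before logs; gradients at
  the clip boundary are finite, and outside it the loss is constant.
- Mean reduction over samples (after summing class nodes) keeps learning
  rates batch-size invariant.
- Grid-search ties on validation macro AUROC break toward the larger
  $\beta$ (the smoother weighting).
- k-fold splits differ in size by at most one; an optional group vector
  (e.g. patient id) keeps grouped records in one partition.

## Known limitations

- The reference backbone is linear-in-pixels up to its fixed filter bank;
  it cannot exploit texture. It exists to exercise the losses and the
  protocol, not to compete with deep backbones, which plug in through the
  same train/evaluate contract.
- With `paper-c` normalization and floor 0, every class with
  $\tilde\alpha_k > 1$ trains without negative-label supervision; its
  score calibration is then meaningless even where its ranking survives.
- Determinism is guaranteed given a seed within this implementation;
  numerical backends with nondeterministic reductions are outside the
  contract.
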