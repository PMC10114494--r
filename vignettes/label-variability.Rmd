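---
title: "Reader label variability and density models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reader label variability and density models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Visual-analogue-scale (VAS) breast-density scores are marked independently
by two expert readers per mammogram, on a 0–100% scale. Readers disagree,
and the disagreement has structure. `densvar` decomposes it into three
components and asks how each affects a learned density model:

1. **Fundamental assessment differences** — systematic, image-dependent
   offsets: readers weight visual attributes (blob count, clustering,
   texture scale) differently.
2. **Distribution warps** — two readers can agree on the *ordering* of
   images while mapping them onto different parts of the scale; modelled as
   a strictly monotone warp of \[0,100\] that fixes the endpoints.
3. **Random error** — zero-mean noise left over after the two systematic
   components.

A deep density model factors into a *representation* (the convolutional
trunk) and a *mapping* (the final linear layer). The package measures the
effect of label variability on each part separately: Method 1 freezes the
representation (a fixed feature extractor) and studies the closed-form
ridge mapping under different label subsets; Method 2 trains small
convolutional models end-to-end under two objectives — averaged labels with
one output, or per-reader outputs under a masked loss — and compares the
representations with identical linear probes.

# The synthetic cohort

No suitable public dataset pairs mammograms with multi-reader VAS scores,
so every experiment runs on a synthetic cohort whose ground truth is known
exactly.

**Images.** Each subject (woman) contributes four views (RCC, LCC, RMLO,
LMLO). An image is a darker half-elliptical breast mask on which
Gaussian-profile "dense tissue" blobs are accumulated until a target
fraction of the mask is covered; the recorded `true_density` is the
*achieved* covered percentage, so the ground truth is exact by
construction. Subject-level density targets are drawn from Beta(2, 3.5)
scaled to \[0,100\] (right-skewed, like a screening population); the four
views share the subject target with per-view jitter of SD 2 VAS points.
Blob amplitude is jittered per image (uniform on \[0.45, 0.8\]) so raw mean
intensity is an informative but imperfect proxy of density (rank
correlation above 0.9 across a cohort, verified in the tests); a model that
only measures brightness therefore has headroom left.

What the generator does **not** emulate: radiographic texture, scanner
physics, pectoral muscle, lesions, intra-reader drift over time. Passing
tests show that the pipeline recovers the configured label-variability
phenomena from images that carry a learnable density signal — they do not
certify performance on real mammograms.

**Readers.** A pool of m = 13 profiles (the default mirrors the included
panel size; configurable). Each reader has:

- a warp `w(x) = 100 * pbeta(x/100, a, b)` with `(a, b)` log-normal around
  identity (log-SD 0.5) — strictly monotone, endpoint-fixing;
- bias weights on the images' standardized texture attributes, normal with
  SD 3 VAS points per unit;
- shared random-error SD of 8 VAS points;
- a gamma-distributed workload weight.

A score is `clip(w(true_density) + bias·texture + noise, 0, 100)`; clipping
comes last because the VAS scale is bounded. The warp and bias magnitudes
are free parameters of the generator; the defaults were fixed once, at
design time, to produce inter-reader scatter and distribution differences
of the size seen in published reader-pair comparisons.

**Assignment.** Each image is read by exactly two distinct readers. Pairs
are drawn with probability proportional to the product of workload weights
times a per-pair log-normal *rota affinity* (log-SD 1.5), modelling readers
who work in partially fixed partnerships. This concentrates reading into a
handful of heavy pairs so that per-pair subsets are large enough to model
at desk scale; `affinity_sd = 0` recovers independent workload-weighted
pairing.

**Case-control subset.** Exactly `n_cases` cases are sampled without
replacement with odds `exp(slope * (density - 50))`; each case is matched
with three controls nearest in age (a single synthetic matching covariate).
`slope = 0` makes case status independent of density, giving the null
calibration used in the tests.

# Preprocessing

The standardization chain, in order: resize to `target_size` (bilinear),
mirror left-laterality images to the right, clip to the (1, 99) intensity
percentiles, invert, global histogram equalization (256 bins), rescale to
\[0,1\]. The clip percentiles and the equalization variant are unquantified
in the source description, so the common defaults are used and recorded in
the config. Whether inversion precedes equalization is fixed here by the
order the steps are named; this is a convention, not a derived fact.

One consequence worth knowing: histogram equalization is a rank transform
of pixel intensities, so it removes the *global* brightness signal — after
equalization, density information survives in spatial texture (edge
density, blob boundaries), not in the mean pixel value. This is why the
fixed feature bank uses small (3×3) dense patches: they respond to the
fine structure that survives.

# Method 1: the closed-form mapping

Features are extracted by a deterministic, seeded convolutional filter bank
(16 random 3×3 filters, ReLU, mean-pooled over a 4×4 spatial grid: p = 256
features), plus a constant bias column. The mapping is ridge regression in
its pseudo-inverse form,

    w = (X'X + lambda2 * I)^(-1) X' y,

solved by QR of the sqrt(lambda2)-augmented design (never an explicit
inverse). `lambda2` defaults to 1 with unstandardized features, exactly as
the formula is stated; it is exposed as a config entry everywhere.

Predictions come from subject-level 5-fold cross-validation: all images of
a woman share a fold, so no subject leaks across the train/test boundary.
CC and MLO predictions are pooled (concatenated) into one evaluation set.

**Individual-label training.** When training on individual scores, each
(image, reader score) pair is its own row, so an image read by two included
readers appears twice. The CV layer scales `lambda2` by the training fold's
rows-per-image ratio; without this, duplicating rows silently halves the
effective regularization. With it, training on both scores of an image is
exactly equivalent to training on their mean under squared loss — which is
why the training-label choice (averaged vs individual) moves the metrics
far less than the testing-label choice, and why degenerate identical
readers collapse the 2×2 train/test grid to a single value.

**Subset experiments.** Per-reader subsets (that reader's images and
labels) and per-pair subsets (jointly read images, averaged labels) are
fitted with the same CV discipline. Subsets below an inclusion threshold
are reported as excluded, never silently dropped. At desk scale the
thresholds are 1000 images per reader and 512 per pair (roughly 2–4× the
feature dimension); random-filter features need more rows per effective
dimension than pretrained-network features, so the source study's
4,000-image rule is scaled up rather than down-prorated.

# Method 2: end-to-end models and the masked loss

The trunk is three valid-convolution blocks (8, 16, `feature_dim` channels,
stride 2, ReLU) with global average pooling; `feature_dim` defaults to 64
at desk scale. The head maps the pooled features to one output
(*single-predictor*, averaged labels) or m = 13 outputs, one per reader
(*multi-predictor*). The multi-predictor is trained with the masked loss

    loss = sum_i phi_i * (rho_i - d_i)^2,

where `phi_i` is 1 iff reader i scored the image. The mask multiplies the
difference before anything else, so sentinel values in unknown label slots
never enter the arithmetic and the gradient on masked outputs is exactly
zero: head rows of readers absent from training stay bit-identical to
initialization, while the shared trunk receives signal from every image.
The batch reduction divides the masked sum by the number of unmasked terms
so single and multi modes see comparable gradient scales (the per-image
definition fixes only the sum).

Training uses Adam with a learning-rate sweep; the model minimizing
validation RMSE is kept. For the multi-predictor, validation RMSE is
computed on unmasked outputs against their own readers' scores — per-reader
rather than averaged, a convention chosen here. Augmentation is
left-right flip with probability 0.5, rotation uniform in ±10° (the
magnitude is a package choice), and additive Gaussian pixel noise (SD
0.01). Trunk initialization, image order and augmentation draws derive from
sub-seeds of the config seed and are identical across modes, so outcome
differences between single and multi runs are attributable to the
objective. Defaults elsewhere: 30 epochs with early-stop patience 5 on
validation RMSE, batch size 32 — all unstated in the source and fixed here.

**Probes.** Each model is stripped to its pooled representation and the
identical Method-1 ridge mapping (same `lambda2`, same fold plan) is
fitted on top, so differences between models come only from the
representations. The desk-scale control is the *untrained* seeded trunk
(a generic pretrained backbone can be plugged in instead, and the report
should then be relabelled accordingly). Label rules: `Av` trains and tests
on averaged scores; `Ind1`/`Ind2` train per reader and test against
averaged scores, aggregating by reader-mean (SD as uncertainty) or by
pooling predictions (bootstrap CI). Both reuse the same CV discipline as
Method 1 — the source leaves the exact protocol open.

# Evaluation

Spearman rank correlation (average ranks; undefined on constant input and
reported as `NA`, never as 0) and RMSE, with 95% percentile bootstrap
intervals over 1,000 image-level resamples (percentile rather than BCa —
only "bootstrapping" is specified). Reader-level aggregates: `Av1` is the
unweighted mean of per-reader metrics with the between-reader SD; `Av2`
recomputes the metric on the pooled prediction/label pairs — the two are
different statistics, and the test suite pins the distinction.

The case-control readout is the top-versus-bottom quintile odds ratio with
quintile boundaries taken from the control distribution (standard
case-control practice), normal-approximation CI on the log odds ratio, and
a flagged Haldane–Anscombe 0.5 correction for zero cells. The per-subject
density is the mean of the subject's per-image predictions (the
subject-level reduction is unstated in the source; the mean is used here).
Matched strata are not modelled (no conditional logistic regression) —
the marginal quintile OR is the deliverable.

# Problem sizes and numerical choices

The shipped experiments use: 1,000-image cohorts (250 subjects, 32 px) for
the train/test label grid; 5,000-image cohorts (1,250 subjects) for the
subset experiments; 2,500-image cohorts at 64 px with 8 training epochs
for the end-to-end comparison; 1,000 bootstrap repeats; 200-replicate null
simulations for the odds-ratio calibration. These sizes were chosen so the
phenomena of interest are comfortably resolved on a single CPU; all of
them are function arguments, not constants.

Degenerate inputs are handled explicitly: constant images pass through
preprocessing as constants; a rank-deficient design with `lambda2 = 0`
raises an error naming the remedy; undefined bootstrap resamples are
redrawn with a capped retry count; an empty subset yields an exclusion
record.

# Known limitations

- The synthetic images are caricatures; absolute metric values have no
  clinical meaning. Only *relative* patterns (which label rule helps, how
  aggregates order) are informative, and only about the simulated reader
  model.
- The untrained-trunk control is a weaker baseline than a genuinely
  pretrained backbone; the trained-versus-control separation is therefore
  larger here than a transfer-learning study would show.
- The odds-ratio analysis ignores the matching when estimating the CI.
- Per-breast (CC/MLO) averaging of predictions is not implemented; the
  evaluation set is always the pooled per-image predictions.
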