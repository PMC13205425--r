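---
title: "Evolving Gabor filter banks for lesion texture classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving Gabor filter banks for lesion texture classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evogmd)
```

## The problem

Distinguishing melanoma from benign nevi in dermoscopic images is, in large
part, a texture problem: malignant lesions tend to show irregular,
directionally organized intensity patterns while benign lesions look more
uniform and isotropic. evogmd builds a compact descriptor of that texture —
a small bank of Gabor filters whose parameters are *learned* for the
classification task — rather than using a fixed, hand-chosen filter bank.

The pipeline is a classic wrapper optimization:

1. convert each image to grayscale, rescale it, and crop it to the lesion
   region defined by a binary mask;
2. convolve the crop with a bank of `Nf` Gabor filters and summarize each
   response map by its mean and standard deviation, giving a `2 * Nf`
   feature vector;
3. score a candidate bank by the stratified K-fold cross-validated error of
   a linear SVM on those features;
4. evolve the `6 * Nf` filter parameters with differential evolution to
   minimize that error.

## The descriptor

Each filter is a Gaussian envelope times a **sine** carrier,

$$g(x, y) = \exp\!\left(-\frac{x'^2 + \gamma^2 y'^2}{2\sigma^2}\right)
           \sin\!\left(\frac{2\pi x'}{\lambda} + \psi\right),$$

with rotated coordinates $x' = x\cos\theta + y\sin\theta$,
$y' = -x\sin\theta + y\cos\theta$, sampled on an $m \times m$ window centred
at the origin. The six parameters per filter and their search domains:

| parameter | meaning                        | domain        | units        |
|-----------|--------------------------------|---------------|--------------|
| `m`       | window (kernel) side           | 1–20, integer | pixels       |
| `sigma`   | Gaussian envelope scale        | 1–5           | pixels       |
| `theta`   | orientation                    | $[0, \pi]$    | radians      |
| `lambda`  | carrier wavelength             | 1–10          | pixels/cycle |
| `gamma`   | envelope aspect ratio          | 0–1           | –            |
| `psi`     | carrier phase                  | $[0, 2\pi]$   | radians      |

The sine carrier is deliberate: most image-processing libraries default to a
cosine ("real Gabor") carrier, so kernels here are synthesized directly from
the formula rather than delegated to a library Gabor routine. A useful
consequence is that odd-size, zero-phase kernels are antisymmetric and sum
exactly to zero, which the tests exploit.

The response of filter $j$ is a *true* 2-D convolution (kernel flipped, per
the convolution operator) with same-size output. The feature vector is
$F = [\mu_1, \sigma_1, \dots, \mu_{N_f}, \sigma_{N_f}]$ where $\mu_j$ is the
response mean over all $M \times N$ cropped pixels and $\sigma_j$ the
**population** (divisor $MN$) standard deviation. Note the symbol collision:
the envelope scale and the response standard deviation are both
conventionally written $\sigma$; they are distinct quantities
(`gabor_params$sigma` vs. the `sigmaJ` feature columns).

## The optimizer

`run_de()` implements DE/best/1/bin: for each target vector the donor is
$V = \Theta_{best} + F(\Theta_a - \Theta_b)$ with distinct partners $a, b$,
followed by binomial crossover at rate `CR` with one forced donor
coordinate, modulus-reflection bound repair, and greedy one-to-one selection
on strict improvement. Defaults are population 30, $F = 0.8$, $CR = 0.9$,
30 generations, 4 filters (a 24-dimensional vector), and an error threshold
of $10^{-6}$ as an early stop.

Design choices worth spelling out, since each was genuinely open:

* **Mixed-integer handling of `m`.** DE runs in continuous space on
  $[1, 20]$; the window size is rounded (half-away-from-zero) to an integer
  only when a vector is decoded into a bank. This keeps the mutation,
  crossover and repair arithmetic exactly as defined.
* **Repair convention.** Out-of-bound coordinates are folded back as
  $U - |x \bmod (U - L)|$ below / $L + |x \bmod (U - L)|$ above, where
  $\bmod$ is the *truncated* (toward-zero) remainder. R's `%%` is the
  floored variant and gives a different answer for negative values, so the
  package implements the truncated form explicitly; the repair is idempotent
  and always lands inside the box.
* **Partner draws.** $a$ and $b$ are drawn uniformly without replacement
  from the population excluding both the target and the current best. The
  RNG stream order per target is fixed (partner draws, forced crossover
  index, crossover uniforms), so a run replays bit-identically from its
  seed.
* **Stopping.** "Reaches a set error" is read as best fitness at or below
  the threshold, not as an improvement delta.

## The fitness

`make_cv_fitness()` scores a candidate by $E = 1 - \frac{1}{K}\sum_k Acc_k$
of a linear SVM (C = 1, via `e1071`/libsvm) under stratified K-fold
cross-validation (K = 5 by default). Two choices matter:

* **Folds are built once per run** (from `fold_seed`) and reused for every
  candidate, so all candidates in a run are compared on identical
  partitions and fitness differences are never partition noise.
* **Features are z-scored by default**, with statistics fitted on the
  training folds only. Raw response means can reach hundreds while other
  features sit near zero, and a C = 1 linear SVM is scale-sensitive.
  `standardize = FALSE` is available for the raw behaviour, and the flag is
  a visible part of the configuration.

Degenerate inputs are handled explicitly: a training split containing one
class is an error naming the fold; identical feature vectors make the SVM
fall back to a majority vote, so a bank of zero-sum kernels on constant
images scores exactly the majority-class error — a property the test suite
checks because it ties the descriptor, fitness and metrics modules together.

## The two-stage protocol

Stage 1 (`run_stage1()`) performs `n_runs` independent DE runs on the
*training set only*, each with run seed `base_seed + i` used both for the DE
stream and the fold partition (folds fixed within a run, different across
runs). It reports min/median/mean/max/sd of the final errors and selects the
best, median and worst runs (ties broken by seed). Stage 2 (`run_stage2()`)
takes one descriptor, fits a single linear SVM on the full training set
without cross-validation, and reports accuracy, precision, recall and F1 on
the held-out test set, with melanoma (label 1) as the positive class and a
collapse flag whenever the model predicts one class for every test sample.
Collapsed models get precision/recall/F1 of 0 by convention; the accuracy of
a majority-collapsed model equals the majority-class fraction exactly, which
is the standard diagnostic for imbalanced-data failure.

## Preprocessing conventions

* Grayscale uses ITU-R BT.601 weights (0.299/0.587/0.114) — the most common
  convention; the weights are an argument so they can be swapped.
* The full image and its mask are rescaled to 720 × 480 first (bilinear for
  images, nearest-neighbour plus re-thresholding for masks, so masks stay
  binary), then masked and cropped. Pixels outside the mask are zeroed
  before cropping to the mask's tight bounding box; zeroed pixels inside
  the bounding box participate in the $\mu/\sigma$ statistics, which average
  over the whole cropped frame.
* Coordinates are row-major: x is the row index, y the column index.
* Border policy for convolution is edge replication, chosen so the
  constant-image/zero-sum-kernel identity holds exactly. Even-size windows
  sample the formula at symmetric half-integer offsets (no anisotropic
  bias); the convolution anchor for even sizes is the `floor(m/2)` cell.

## The synthetic benchmark

`generate_dataset()` builds a fully in-package two-class benchmark: class 0
is a sinusoidal grating at one orientation, class 1 a grating at another
orientation plus — scaled by a heterogeneity parameter — a second grating
rotated a further 60°, emulating directionally disorganized texture. Each
sample gets a random carrier phase, Gaussian pixel noise, and a random
filled-ellipse lesion mask; intensities are rounded to 8-bit so samples
survive PNG round trips exactly. The defaults (20 samples per class,
64 × 64 pixels, orientations 0 and $\pi/2$, wavelength 6, noise sd 5,
heterogeneity 0.5, semi-axes 20–28 px) are the package's standard benchmark
conditions: the class difference lives purely in orientation, never in mean
intensity, so succeeding requires genuinely directional features. Images are
small so that full repeated-DE experiments finish in tens of seconds;
720 × 480 operation is configuration-selectable.

What the generator does *not* emulate: hair and acquisition artifacts,
colour information, lesion-shape cues, intra-class texture diversity, or the
class imbalance of clinical archives. Passing the recovery benchmark shows
the optimizer finds orientation-discriminative filters under controlled
conditions; it does not certify clinical performance on dermoscopic data.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use the benchmark sizes above
with DE population 10, 10 generations and 2 filters, 5-fold CV, and 31
independent runs — small enough to run routinely on one core, large enough
that the recovery property (cross-validated error ≤ 0.05 in at least 27 of
31 runs, held-out accuracy ≥ 0.9 for the median descriptor) is a meaningful
end-to-end check. Every stochastic step — dataset generation, fold
assignment, DE — is seeded, and a run's seed replays it exactly.

## Limitations

* The wrapper fitness refits K SVMs per candidate; cost grows linearly with
  population, generations, images and filter window area. For full-scale
  imagery expect minutes-to-hours rather than seconds.
* With very small sample sets the CV error is coarse (multiples of one
  misclassification), so many candidates tie at the optimum and the selected
  bank is not unique — only its discriminative behaviour is.
* The SVM is fixed to a linear kernel with C = 1 by design; no
  hyperparameter search is performed or supported.
* Only binary classification is supported; metrics fix label 1 as the
  positive class.
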