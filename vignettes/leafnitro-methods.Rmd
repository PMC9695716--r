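---
title: "Methods: leaf nitrogen prediction from calibration-board images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leaf nitrogen prediction from calibration-board images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafnitro)
```

## The problem

Leaf nitrogen status drives chlorophyll production and hence yield in rice;
monitoring it non-destructively supports precise fertilization. `leafnitro`
implements an image-based estimation chain: a leaf is photographed lying on
a calibration board whose squares have a known physical size, the leaf is
segmented, its area is converted from pixels to cm² through the board, the
green-channel colour statistics are extracted (leaf greenness tracks
chlorophyll and so nitrogen), and a regression model maps
(area, G-mean, G-variance) to nitrogen content in g/kg. Two phenological
stages are modelled separately — stem elongation ("growing", nitrogen
mostly 9–11 g/kg) and flowering ("mature", 15–19 g/kg) — because the
feature-to-nitrogen relation shifts between them.

## Calibration model

Let a segmented mask contain $A$ foreground pixels. With $S_1$ the physical
area of one board square (cm²) and $S_2$ its pixel area in the same image,
the calibration coefficient is

$$K_c = S_1 / S_2 \quad [\mathrm{cm^2/px}], \qquad
  \text{leaf area} = A \cdot K_c .$$

For linear measurements the analogous scale ratio $K = A/L$ (actual over
pixel size) and feature size $F = K M$ are exposed separately
(`scale_ratio()`, `actual_size()`); only the $K_c$ path is dimensionally
valid for areas, so `extract_features()` uses it exclusively. $S_2$ is
estimated as the **median** pixel area of detected board squares, which
makes it robust to squares partially covered by the leaf. The physical
square size defaults to 1 cm and is configurable (`board_square_size_cm`);
the colour statistics are computed **over the leaf mask only** — board
pixels would otherwise dominate the G-channel mean.

The G-mean is the frequency-weighted histogram mean
$\sum_i x_i f_i / \sum_i f_i$, identical to the plain per-pixel mean; the
G-variance is the population variance of the same pixels. Both are reported
per leaf.

## Image pipeline

* **Denoising** — locally adaptive Wiener-style smoothing per channel: with
  local mean $m$ and variance $v$ in a 5×5 window and noise floor
  $\nu = \overline v$, the output is $m + \max(v-\nu,0)/\max(v,\nu)\,(x-m)$.
  Flat regions are smoothed hard, structure preserved; a constant image is
  returned unchanged.
* **Leaf segmentation** — green dominance ($G > R + 20$ and $G > B + 20$
  gray levels), with an Otsu fallback on the $G-(R+B)/2$ map that is
  accepted only if the candidate foreground is genuinely green-dominant
  (mean map value ≥ 10), so a leafless board errors out rather than
  "finding" a leaf. The raw mask is cleaned by opening/closing with a
  2-px disc, interior holes are filled, and the largest component is kept.
* **Edge extraction** — Sobel gradient magnitude, hysteresis thresholds at
  the 70th/90th percentiles of the non-zero gradients (the weak threshold
  is additionally capped at half the strong one: on few-valued gradient
  maps raw percentiles can coincide and break the edge ring). Because the
  Sobel response to a step edge is one ring *each side* of the contour, the
  closed, hole-filled band is eroded by one 4-connected step before the
  boundary — foreground pixels with a 4-neighbour in the background — is
  returned. On a binary rectangle this reproduces the rectangle's own
  boundary pixel count exactly.
* **Board detection** — non-leaf pixels are classified into the two board
  colours (2-means, deterministically initialized at the darkest/brightest
  non-leaf pixels); each colour class is labelled into 4-connected
  components. Components touching the border, smaller than 64 px, or
  filling under 80% of their bounding box (squares are solid; noise blobs
  are ragged) are dropped, then areas outside ±20% of the median are
  discarded as occluded partials. Fewer than 4 surviving squares is an
  error.
* **Connectivity** — all component labelling is 4-connected. This is
  required for checkerboards (same-colour squares touch at corners and
  would merge under 8-connectivity) and makes no difference for a filled
  leaf mask. Coordinates are (row, column), masks are 0/1 matrices.

## The hybrid regressor

The predictor is PLS regression on Gaussian-RBF activations — a kernel-PLS
architecture. Features are standardized (predictions are therefore
invariant to affine rescaling of any input feature); $c$ centers are placed
by seeded k-means on the standardized features; the activation matrix has
entries

$$H_{ij} = \exp\!\left(-\frac{\lVert x_i - c_j\rVert^2}{2\sigma^2}\right)
  \in (0,1],$$

and a univariate NIPALS PLS with $a$ latent variables maps centered
activations to centered nitrogen. At full latent rank PLS coincides with
the least-squares fit on $H$; with $a$ small it regularizes, which matters
at the study's protocol scale of 35 training samples per stage.

Hyperparameters $(\log\sigma, c, a)$ are tuned by a real-coded genetic
procedure minimizing the absolute-error fitness
$F = k\sum_i |y_i - o_i|$ (default $k=1$; $k$ is a monotone rescaling and
cannot change any selection) computed on 5-fold cross-validated
predictions, with fold assignment fixed per run so all genomes are scored
on identical splits. Selection is roulette with inverse-fitness weights
$p_i \propto 1/(F_i+\varepsilon)$, $\varepsilon = 10^{-12}$; crossover is
an arithmetic blend (probability 0.7); mutation is Gaussian per gene
(probability 0.1). Two optimizer design choices proved important on sharp
fitness landscapes and are the package's defaults:

* **Latin-hypercube initialization** — each gene is stratified across its
  search range, so narrow basins are sampled by some member even when they
  occupy a few percent of the range;
* **mixed-scale mutation** — half of the mutation draws anneal by a factor
  0.85 per generation (fine-tuning near convergence), half keep the full
  scale (retaining global reach throughout).

Elitism (1 genome) guarantees the best-per-generation fitness is
non-increasing. Integer genes are rounded and clamped; an infeasible pair
($a > c$) is repaired by clamping. The final model is refit on all training
rows with the best genome. All stochastic steps flow from the single
config seed, so a rerun is bit-identical, and the JSON model serialization
is canonical (full precision, fixed field order) so identity can be
audited by file comparison.

A note on identifiability: on small noiseless toy problems with *fixed*
centers, the cross-validated optimum of $\sigma$ can sit well above the
generating width — per-fold re-standardization jitters the effective
center positions, and wider kernels are more forgiving of that. From about
150 samples in one dimension the CV optimum coincides sharply with the
generating $\sigma$; the test suite's recovery check uses that regime.

## Baselines

* **GRL** — ordinary least-squares multiple linear regression of nitrogen
  on (area, G-mean, G-variance) plus intercept.
* **GRM** — general regression (Nadaraya–Watson): a Gaussian-kernel
  weighted convex combination of training targets on the standardized
  feature scale, bandwidth chosen by leave-one-out CV over a 25-point
  log-spaced grid; a prediction at vanishing kernel mass falls back to the
  nearest training target.

## Evaluation statistics

MAE, RMSE and MAPE, with the *predicted* value in the MAPE denominator by
default (a documented switch selects the conventional actual-value form);
MAE/RMSE are in g/kg, MAPE is a fraction internally and percent in
reports. The per-sample signed error rate is
$E = (\hat y - y)/y \times 100\%$. Fit diagnostics regress predicted on
actual (predicted on the vertical axis) and report slope, intercept, $R^2$
and Pearson $r$; for a single sample RMSE equals MAE by construction.

## The synthetic test bench

Real acquisitions from the original field protocol are not distributable,
so the package ships a generator with exact ground truth.

* **Scenes** (`render_scene()`): an alternating two-colour checkerboard
  (the board's appearance beyond "known square size" is a free choice;
  a checker gives unambiguous square boundaries), with a leaf drawn as an
  ellipse/superellipse/rectangle by a *hard pixel-centre inclusion test* —
  no anti-aliasing at mask level, so pixel counts are exact; colour jitter
  and Gaussian frame noise are added afterwards and quantized to 8 bits.
  Ground truth records the mask, pixel and cm² area, true per-square pixel
  area, and the G-mean of the final rendered leaf pixels.
* **Datasets** (`simulate_dataset()`): features drawn uniformly from
  realistic per-stage ranges (area 10–40 cm², G-mean 80–180, G-variance
  50–600); nitrogen is a sum of Gaussian bumps over normalized feature
  space — one broad bump setting the stage level plus two narrower
  positive/negative bumps curving the surface — plus Gaussian noise
  (default SD 0.2 g/kg), clipped into the stage range (9–11 or
  15–19 g/kg). Clipping after noise reproduces hard observed ranges. The
  bump form matches the RBF hypothesis class deliberately, so parameter
  and signal recovery are meaningful tests.

What the bench does *not* emulate: venation, specular lighting,
perspective, shadows, multi-leaf boards, or feature distributions of any
particular cultivar. Passing tests demonstrate the chain is correct and
self-consistent, not that field accuracy matches any published figure.

## Problem sizes and defaults

The test suite exercises: 20 rendered scenes (480×480 px, 40-px squares)
for calibration recovery (area within 2%, G-mean within 1 gray level);
100-case brute-force oracles for every formula; a 200/100 train/test
simulation for signal recovery (hybrid test RMSE ≤ 0.3 g/kg at noise SD
0.2, and below the linear baseline); a 150-point one-gene toy for the
GA-versus-grid check; and the 35/10 per-stage protocol for end-to-end
determinism. Experiment defaults use a GA of population 16 and 12
generations, which is ample for three genes on three features; the toy
recovery uses population 30 and 25 generations because its basin is
narrow.

## Known limitations

Single leaf per scene; the two board colours must be distinguishable and
different from leaf green; MAPE's predicted-value denominator is
non-standard (switchable); GRL/GRM are this package's concrete readings of
loosely specified baselines; the GA optimizes three hyperparameters, not
network weights.
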