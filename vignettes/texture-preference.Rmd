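---
title: "Naturalistic texture preference and sparse firing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Naturalistic texture preference and sparse firing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texsparse)
```

## The scientific question

Neurons in higher visual areas (V2, V3, V4) respond more vigorously to
images carrying the higher-order statistical dependencies of natural
textures than to spectrally matched noise, while V1 neurons barely
distinguish the two. `texsparse` implements, at desk scale, the full
analysis chain used to study this signature in hierarchical models: paired
stimulus synthesis, a hierarchical nonnegative sparse-coding network
(SHMAX), modulation and sparseness metrics, and the bespoke statistics that
tie them together.

The central quantity is the per-unit **modulation index**

$$ m_u = \frac{1}{|P_u|} \sum_{p \in P_u}
   \frac{r^{CM}_{u,p} - r^{SM}_{u,p}}{r^{CM}_{u,p} + r^{SM}_{u,p}}, $$

where CM denotes a structured (correlation-matched) image, SM its
phase-scrambled counterpart, and $P_u$ the pairs for which the unit
responded to at least one member (both-zero pairs are excluded; a unit with
no valid pair is excluded from the population summary). The **PMI** is the
mean index over a set of units. Sparseness is measured four ways; the
primary one is lifetime sparseness $S = 1 - (E[r])^2 / E[r^2]$ across
stimuli.

## Stimulus synthesis

**Phase randomization.** SM images are produced by randomizing Fourier
phases while conserving the amplitude spectrum exactly: phases are drawn
i.i.d. uniform over one half-plane and mirrored with conjugate symmetry,
the DC phase is fixed at 0 (the image mean is untouched), and the
self-conjugate Nyquist bins of even-sized images only have their sign
randomized. Odd image sizes are rejected rather than handled ambiguously.
No clipping is applied to the output; the inverse transform's imaginary
residue is checked against a 1e-9 relative bound before being discarded.

**Structured textures.** True correlation-matched synthesis (iterative
projection onto measured statistics) is out of scope; instead
`synth_texture()` builds textures generatively: even-phase Gabor elements
placed along smooth random-walk contours over a weak noise floor. Four
family-level knobs control the statistics downstream analyses care about:
`density` (elements per 1000 px²), `ori_conc` (how tightly element
orientation follows the contour tangent), `curvature` (contour turning
rate), and `coupling` (the probability that an element is repeated at the
same location at twice the scale, which is what creates cross-scale phase
alignment). `build_corpus()` samples families from a Latin hypercube over
these knobs (density 8-30, coupling 0.3-1) so families are distinguishable
and all carry genuine higher-order structure; each image is paired with its
own phase scramble. These ranges were fixed once, as generatively sensible
values, when the generator was written.

What the generator does *not* emulate: natural-image power spectra beyond
what Gabor elements induce, luminance nonstationarity, and the full
covariance structure of the 1,104-parameter texture-statistics model.
Passing tests therefore demonstrate correctness of the machinery and the
qualitative signature on synthetic structure, not quantitative agreement
with results obtained on natural texture corpora.

**Preprocessing.** Images are resized (bilinear, box-average anti-aliasing
on downscale), mean-subtracted per image, and resized to the model's input
size; the conventional protocol is 128 px working size and 224 px model
size. Resizing is hand-rolled because no installed package offers
anti-aliased bilinear resampling behind a small surface.

## Texture statistics

The seven statistic groups (pixel marginals; sub-band spectral energies;
linear and energy correlations across position, scale and orientation) are
computed from an undecimated analytic filter bank: log-Gabor transfer
functions occupying one frequency half-plane, four octave-spaced scales
(finest wavelength 4 px) by four orientations by default. The real and
imaginary parts of the analytic response are the even/odd quadrature pair;
the modulus is the energy (complex-cell) response. Because filtering is
frequency-domain and undecimated, all response maps live on the image grid
and cross-scale correlations need no resampling.

Two numerical choices matter:

* **Cross-scale linear correlations use the phase-doubled coarse
  response** $\mathrm{Re}(c^2/|c|)$. A plain correlation between two
  linearly filtered maps is a functional of the amplitude spectrum alone
  (Parseval) and would be *blind* to phase scrambling; doubling the coarse
  phase aligns it with fine-scale components of half the wavelength, which
  is precisely the structure scrambling destroys.
* **Angular bandwidth** is narrow (sd = orientation spacing / 2.5) so that
  orientation-energy correlations on white noise are near zero and measure
  genuine cross-orientation co-occurrence rather than passband overlap.
  Correlation estimates at the coarsest scale have few effective spatial
  degrees of freedom; tests that assert near-zero baselines therefore
  restrict themselves to the finer scales.
* **Numerically silent sub-bands are gated.** A sub-band carrying less
  than 1e-4 of the stimulus RMS (e.g. orientations orthogonal to a
  grating) has nothing to correlate but round-off; its correlation
  statistics are reported as 0, as are correlations of maps that are
  constant up to numerical noise (the energy response to a pure grating).

Position correlations are Pearson correlations between a response map and
its shifted copy over the valid overlap, for offsets in
$\{-3..3\}^2 \setminus \{0\}$ de-duplicated by point symmetry. Constant
images are degenerate: all groups are reported as zeros with a flag, so
corpus-scale batch runs survive pathological members. The raw parameter
count depends only on the bank configuration (834 for 3 scales, 1106 for
4); the grouped structure, not the raw count, is what the downstream
regression needs.

For the modulation regression, raw statistics are transformed by signed
square root and z-scoring, then reduced by PCA *within each group* to the
smallest component set covering more than 90% of variance (threshold
configurable). Group contributions to the full-model $R^2$ are decomposed
by averaging incremental $R^2$ over all group orderings, computed exactly
via the subset identity at $2^G$ cost and refused for more than 12 groups.

## The SHMAX model

Coding layers solve the nonnegative sparse-coding problem

$$ \min_{s \ge 0} \; \lVert x - A s\rVert_2^2 + \lambda \lVert s\rVert_1,
   \qquad \lVert a_i \rVert_2^2 \le 1, $$

patch-wise at a stride (patch-wise independent coding matches the
per-patch objective; convolutional sparse coding with a shared
reconstruction is deliberately not used). The solver is cyclic coordinate
descent on the Gram matrix, which is deterministic and testable against
the KKT conditions; dictionaries are learned by alternating batch coding
with a block column update (each column minimized in closed form given the
codes, then projected to the unit ball), so the objective is non-increasing
across outer iterations. Atoms are initialized from random training
patches. Convergence uses a fixed iteration budget with a 1e-6 relative
objective-change early stop. Codes are computed to a 1e-9 coordinate
tolerance during training and 1e-8 during forward passes; `encode()`
defaults to 1e-10 for analysis use.

Max pooling follows each coding layer. The default desk-scale architecture
has three big layers (kernels 7/5/3, strides 2/1/1, 2x2 stride-2 pooling,
32/48/64 atoms) sized for 64-96 px inputs; λ defaults to 0.15 for the
first two big layers and 0.1 above, and the sweep grid
{0.01, 0.02, 0.05, 0.1, 0.25, 0.35, 0.45} is the conventional one. The
five-big-layer geometry of the classic AlexNet stack is available for the
receptive-field and unit-count calculators. The "response of a big layer"
is its final maps (after pooling), recorded per run.

**Two-path receptive-field control.** The lower big layer is split into
set *b* (enlarged kernel $k_b = k_c + (k_p-1)s_c + (k_a-1)s_c s_p$) and
set *c* (baseline kernel); the upper layer's set *a* reads the pooled
set-*c* path, so the receptive field of *a* equals that of *b* and exceeds
that of *c* by construction. Asymmetric zero-padding keeps both sets' maps
the same size. Responses for this control are taken at the coding layers
themselves — they are the units whose receptive fields the construction
equates; taking them after pooling would add different receptive-field
increments to the two paths.

## Bespoke statistics

The **ranking distance** between permutations $X, Y$ of $1..n$ is
$D = \sum_i \lvert \log(i / f_Y(x_i)) \rvert$ with the natural logarithm
(with base-10 logs the permutation-test null would sit far too low to
produce p-values in the 1e-3 range that the test is known to produce at
$n = 25$). Its permutation test samples pairs of uniform permutations and
reports the fraction of null distances *strictly* smaller than the
observed one — no continuity correction, though a corrected variant is
available. The **random-sampling t-test** draws a fixed number of units
(default 100) without replacement from each group independently, 500
times, and averages the per-draw one-tailed t-test p-values. The
**per-unit randomization test** swaps the CM/SM roles of each valid pair
independently with probability 1/2 (preserving pair structure; a
global-relabel variant is available since the shuffling convention is
genuinely ambiguous), recomputes the index 10,000 times, and calls a unit
significantly positive when the fraction of the null strictly above the
observed index falls below 0.05. "Did not respond" means exactly zero:
rectification and nonnegative coding produce hard zeros (an epsilon
threshold is configurable).

## The synthetic response generator

To validate every estimator without a trained network,
`gen_response_matrix()` draws CM responses from gamma distributions with
shape $k(1+m_u)$ and SM responses with shape $k(1-m_u)$ at a common scale,
so $r_{CM}/(r_{CM}+r_{SM})$ is Beta-distributed and the per-pair index is
*exactly* unbiased for $m_u$ before thinning. Zeros are imposed by
independent thinning at the unit's non-firing probability, giving the
closed forms used by the recovery tests:
$E[\hat m] = m(1-nf)/(1+nf)$ and lifetime sparseness
$S = 1 - (1-nf)/(1 + m^2 + 1/k)$. `gen_tornado()` couples the modulation
spread to the unit's sparseness with an optional positive-skew fold,
reproducing the widening, positively skewed sparseness-modulation scatter
seen in trained models. The lifetime-sparseness ratio estimator carries an
$O(1/n_{\text{stimuli}})$ downward bias; recovery experiments therefore
use 600 pairs per unit, where the bias is well inside Monte-Carlo error.

## Problem sizes

The test and validation experiments run at deliberately small scale,
chosen once as representative: corpora of 8 families by 6 images at 64 px
(the full 25 x 40 protocol is exercised for corpus construction), training
on 12 images with 80 patches per image and 8 dictionary iterations, 10
seeded repetitions for model-level claims, 1e6 null samples for the
ranking-distance test, and 10,000 shuffles for per-unit randomization
tests.

## Known limitations

* The structured-texture generator is a stand-in: pipelines accept
  externally synthesized correlation-matched corpora (`read_corpus()`),
  and quantitative results on synthetic families should not be compared
  numerically to results on natural textures.
* At desk scale the bottom layer shows a *negative* PMI: structured
  textures concentrate energy in sparse elements over a weak noise floor,
  so first-layer codes are zero over much of the image while the
  equal-variance scramble drives weak responses everywhere. The layer
  *trend* (top above bottom) is robust; the per-layer values are not
  comparable to ImageNet-scale models.
* The random-weight control retains a strong positive top-layer modulation
  here. This is informative rather than a defect: the λ-threshold of
  nonnegative sparse coding plus max pooling is itself a sparsifying
  nonlinearity, and on heavy-tailed structured textures versus their
  gaussianized scrambles even random unit-norm atoms respond more
  selectively to structure. Plain-ReLU convolutional stacks, where the
  random-weight control is classically reported to erase the signature,
  have no such threshold. The control is reported as measured.
* Training is layer-wise and batch; there is no GPU path, no CNN
  backpropagation, and no local response normalization.
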