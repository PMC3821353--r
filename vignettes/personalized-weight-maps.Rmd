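---
title: "Personalized weight maps for binary-pattern finger-vein matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized weight maps for binary-pattern finger-vein matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinpwm)
```

## The problem

Finger-vein recognition verifies identity from the pattern of blood
vessels inside a finger, imaged with near-infrared light that hemoglobin
absorbs: veins appear as dark curvilinear structures on brighter tissue.
Because raw vessel segmentation is fragile on low-contrast images, a
widely used alternative is to convert the whole image into a long binary
code with a local binary-pattern operator and compare codes with Hamming
distance. Every bit then encodes a local intensity comparison, and
matching never requires an explicit vessel map.

Plain Hamming matching treats all bits as equally informative. They are
not: across repeated captures of the same finger some bits reproduce
almost deterministically while others flip essentially at random
(sensor noise, small placement shifts, flat tissue regions with no
intensity gradient). The premise of this package is that each enrolled
finger should carry its own per-bit reliability profile, and that this
profile should weight the comparison.

## Feature codes

Two operators are provided.

**LBP.** For every interior pixel, the eight neighbors of its 3×3
kernel are compared against the center; neighbor minus center is
sign-thresholded with $s(x) = 1$ for $x \ge 0$ and $0$ otherwise. The
eight bits per pixel start at the top-left neighbor and proceed
clockwise (any fixed convention yields identical Hamming geometry; the
convention is recorded in the code's operator tag). An $h \times w$
image yields $(h-2)(w-2) \cdot 8$ bits.

**LLBP.** The line operator compares pixels along a horizontal and a
vertical line of odd length $N$ (default 21) against the line's center
pixel, giving $N - 1$ bits per direction per pixel; the horizontal and
vertical codes are concatenated. Pixels whose kernel or line would
leave the image are skipped rather than padded: padding would invent
intensities and perturb exactly the bit-stability signal the method
measures. The decimal-weighted magnitude
$\sqrt{\mathrm{LLBP}_h^2 + \mathrm{LLBP}_v^2}$ is exposed as a
diagnostic view only; matching always uses the concatenated binary
code. At the default 96×64 image size and $N = 21$ the LLBP code is
181,760 bits long.

Both operators depend only on the sign of intensity differences, so all
codes are invariant to any strictly increasing intensity transform of
the image — the property that makes binary patterns robust to
illumination changes, and one of the package's property tests.

## The personalized weight map

Let a class (one enrolled finger) have $k \ge 2$ training codes. For
bit $i$, write $m_1$ for the number of training codes with a 1 there
and $m_0 = k - m_1$. Averaging the agreement indicator over all
$k \times k$ ordered comparisons of the training codes — including
self-comparisons — gives the stability

$$p_i = \frac{m_1^2 + m_0^2}{(m_1 + m_0)^2} \in [0.5,\, 1],$$

which is rescaled to the weight $w_i = 2 p_i - 1 \in [0, 1]$. The
implementation uses this closed form; a test validates it against the
literal double sum on random inputs. Self-comparisons must be included:
without them the closed form above does not hold (for $k = 2$ the
excluded version would give $p_i \in \{0, 1\}$ rather than
$\{0.5, 1\}$).

With $k$ training codes the weights are quantized to the $k + 1$ values
reachable by $m_1 = 0..k$; for $k = 8$ these are
$\{0, 0.0625, 0.25, 0.5625, 1\}$ and for $k = 2$ only $\{0, 1\}$. This
quantization is why more training samples help: the weight map resolves
stability more finely. Training with $k = 1$ is refused — a single code
carries no stability information.

A probe code $B$ is scored against an enrolled code $A$ of a class with
weight map $W$ by

$$S_{AB} = 1 - \frac{\sum_i w_i \, (a_i \oplus b_i)}{\sum_i w_i},$$

accepting when $S_{AB}$ strictly exceeds the operating threshold. The
weight map is always the *enrolled* class's — the score is asymmetric
in the two roles. Two exact reductions are built into the test suite:
all weights 1 recovers $1 -$ Hamming distance, and 0/1 weights recover
best-bit matching. The best-bit map (mask of bits constant across all
training codes, i.e. weight exactly 1) is provided as `train_pbbm()`;
it is literally the special case of the weight map that discards all
partially stable bits. If a bit takes value 1 i.i.d. with probability
$\pi$ across captures, the trained weight converges to $(2\pi - 1)^2$
as $k \to \infty$ — the squared bias of the bit — which is the
parameter-recovery property the synthetic generator is tested against.

## Preprocessing

Raw captures pass through three steps before feature extraction, each a
deliberate design choice where the field has no single convention:

* **ROI extraction** — Otsu threshold, morphological closing of the
  foreground (so dark vein strokes reaching the finger boundary cannot
  split the region), largest connected component, tight bounding box.
  If the mask is empty or covers the frame (e.g. a constant image), the
  central crop spanning the middle 75% of each dimension is used and a
  warning is raised. Galleries that are already cropped can skip the
  step (`roi = FALSE`, CLI flag `--pre-cropped`).
* **Size normalization** — bilinear resampling to 96×64 (configurable).
  The resampler uses pixel-center alignment, so resampling an image to
  its own size is exact and constant images stay constant; interpolated
  values are convex combinations and never leave the input range.
* **Gray normalization** — global min–max stretch to [0, 1]; constant
  images map to 0.5. The stretch is rank-preserving and idempotent, and
  no vein-enhancement filtering is applied.

Images are handled internally as numeric matrices in [0, 1]; 8-bit
files are divided by 255 on read.

## Evaluation protocols

**Verification.** Each class trains on its first `k_train` samples and
tests on the rest. Genuine scores are all unordered pairs among each
class's first `n_test_all` test samples; imposter scores pair each
class's first `n_test_imposter` test samples against every other
class's first `n_test_imposter`, both class orders counted (the
enrolled role, and hence the weight map, differs between the two
directions). With 136 classes, 10 test samples and 2 imposter samples
this yields exactly 6,120 genuine and 73,440 imposter scores — a
combinatorial identity in the acceptance tests.

`compute_eer()` sweeps the threshold over all observed scores. FAR is
the fraction of imposter scores strictly above the threshold and FRR
the fraction of genuine scores at or below it, matching the strict
acceptance rule, so the swept curve is monotone by construction. The
equal error rate interpolates linearly between the two sweep points
where FAR − FRR changes sign; FRR at 0.1% FAR and FAR at 0.1% FRR are
read off the same curve, taking at each level of the conditioning rate
the best (smallest) achievable value of the other before interpolating.

**Identification.** One template per class (deterministically the first
non-training sample by default — reproducibility is preferred over the
random choice, which remains available through `template_index`), the
remaining samples are probes. Each probe is scored against every
template under the template class's weight map and ranked; ties are
resolved pessimistically (the true class is placed after every template
scoring at least as high), so reported ranks are conservative and
deterministic. The cumulative match characteristic, rank-one rate and
the lowest rank of perfect recognition summarize the ranking.

`training_size_sweep()` fixes the last `n_test` samples of each class
as the test set and varies the number of training samples, running
plain, best-bit and weighted matching through the identical scoring
pipeline so their results are directly comparable.
`random_split_repetitions()` repeats the verification protocol over
seeded random training subsets and summarizes EER spread.

## Synthetic data

Two generators make every pipeline stage testable without a dataset.

**Code populations** (`generate_code_population()`) directly emulate
the statistical structure the weight map exploits: each class has a
uniform random template code, and each sample flips bit $i$ with that
position's flip probability — a fraction `f_stable` of positions flip
with `q_low`, the rest with `q_high`. Ground truth (templates and flip
probabilities) is returned for parameter-recovery tests. The defaults
— 20 classes × 16 samples, 256-bit codes, 30% stable positions,
`q_low = 0.05`, `q_high = 0.45` — were fixed once, by the following
reasoning: with codes thousands of bits long, the binomial
concentration of the Hamming score separates even noisy classes
perfectly and every matcher trivially reaches EER 0, so nothing can be
compared; 256 bits with heavy noise on 70% of positions puts plain
Hamming matching in the few-percent EER range, which is where published
binary-pattern systems actually operate, while weighted matching still
reaches near-zero EER with 10 training samples. Because bit flips are
i.i.d. given the template, these populations do not model the spatially
correlated errors of real imagery (a translated finger flips whole
contiguous bit runs); passing tests on them validates the statistical
machinery, not robustness to geometric distortion.

**Vein images** (`generate_vein_image_class()`) render a bright
superelliptic finger region on a dark background, crossed by smooth
random dark curves (spline strokes) that constitute the class's fixed
vascular geometry; each sample receives a random rigid translation
(sd `warp_sd` = 1 px) and Gaussian pixel noise (sd `noise_sd` = 0.04).
This is deliberately minimal realism: dark curvilinear structure with
intra-class geometric consistency is all the matching method consumes.
No skin-scattering optics, non-rigid deformation or capture-device
model is attempted, so image-based tests demonstrate pipeline
correctness and genuine/imposter separation, not field accuracy.

All generator randomness flows from one explicit seed through a local
RNG stream that restores the caller's state afterwards; identical seeds
give bit-identical galleries.

## Numerical and degenerate-input choices

* `s(0) = 1` exactly, including for real-valued images where exact
  intensity equality is rare but possible; a constant image therefore
  produces an all-ones code under every operator.
* Codes are stored bit-packed eight-to-a-byte with an explicit logical
  length; padding bits are forced to zero so XOR popcounts (computed
  via a 256-entry byte table) never see them.
* Weight maps summing to zero are rejected at match time
  (`degenerate_weights`), and empty best-bit masks at mask use
  (`degenerate_template`); best-bit *training* on fully unstable codes
  warns but still returns the mask, so callers can inspect it.
* Template files store weights as 64-bit IEEE doubles. Weights are
  dyadic-looking but generally not float32-representable (e.g. 0.64 at
  $k = 10$), and the serialization contract here is a bit-exact round
  trip, so single precision would silently violate it.
* Threshold comparison is strict (`>`); the EER sweep covers all
  observed scores plus a sentinel below the minimum, so the choice does
  not affect swept metrics.

## Problem sizes used in the shipped tests

The test suite and the reproduction script run entirely on synthetic
data at desk scale, chosen to exercise every code path with comfortable
margins: oracle comparisons on ~100 random images up to 30×30 and ~100
random code sets; parameter recovery at $k = 2000$ codes × 200 bits
(assessed on per-flip-probability group means, since an individual
bit's estimate retains $O(1/\sqrt{k})$ sampling noise); protocol
combinatorics at full 136-class scale with 16-bit codes; matcher
comparisons on the default 20-class code population; and image
pipelines on 3–4 classes of 64×80 to 120×160 renders.

## Known limitations

* The ROI detector is intensity-threshold based and assumes one bright
  dominant region; it is adequate for the synthetic renders and simple
  captures, not for cluttered scenes.
* No rotation or non-rigid registration is performed beyond cropping,
  and no vein-enhancement filtering (Gabor, curvelet, Ridgelet) is
  applied before code extraction.
* One template per class: multi-template fusion and cross-class score
  normalization are out of scope.
* Synthetic galleries validate correctness and directional claims
  (weighting ≥ masking ≥ uniform; more training samples help); absolute
  error rates on real finger-vein databases cannot be inferred from
  them.
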