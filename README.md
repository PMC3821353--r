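# veinpwm

Finger-vein recognition with **personalized weight maps**: binary-pattern
matching in which every bit of an enrolled finger's feature code carries a
weight measuring how stably that bit reproduces across the finger's
enrollment captures.

## Who this is for

Researchers and engineers working on vascular biometrics (or any
binary-code biometric) who need a complete, reproducible reference
pipeline: feature extraction, per-class reliability weighting, matching,
and the standard verification/identification evaluation harness — all
runnable on built-in synthetic data, with no external database required.

## The method

A near-infrared finger image is preprocessed (ROI crop, bilinear
resampling to 96×64, min–max gray stretch) and converted to a binary code
by a local binary pattern operator:

* **LBP** — per interior pixel, 8 sign-thresholded comparisons against
  the 3×3 neighbors: bit = s(i_n − i_c), with s(x) = 1 iff x ≥ 0;
* **LLBP** — per pixel, N − 1 comparisons along a horizontal and a
  vertical line of odd length N (default 21) against the line center,
  horizontal and vertical codes concatenated.

For a class with k ≥ 2 training codes, bit i seen as 1 in m₁ codes and 0
in m₀ = k − m₁ gets stability

    p_i = (m1² + m0²) / (m1 + m0)²   ∈ [0.5, 1]

(the average of all k×k pairwise agreement indicators, self-pairs
included), rescaled to the weight w_i = 2 p_i − 1 ∈ [0, 1]. A probe code
B is scored against an enrolled code A by the weighted similarity

    S_AB = 1 − Σ_i w_i (a_i ⊕ b_i) / Σ_i w_i

and accepted when S_AB strictly exceeds the threshold. With all weights
equal to 1 this is exactly 1 − Hamming distance; with 0/1 weights it is
the *personalized best-bit map* (PBBM) method, which matches only on the
bits that were constant across training — both reductions are exported
(`train_pbbm()`, `pbbm_similarity()`) and tested exactly.

The evaluation module implements the standard protocols: genuine/imposter
verification scoring with EER, FRR @ 0.1% FAR, FAR @ 0.1% FRR and the
full ROC sweep; identification with CMC curves, rank-one rate and lowest
rank of perfect recognition; seeded random-split repetitions; and a
training-set-size sweep that compares plain, best-bit and weighted
matching through one shared scoring pipeline.

## Worked example

```r
library(veinpwm)

# synthetic population with mixed bit stability: 20 fingers, 16 captures
pop <- generate_code_population(seed = 1)

# compare uniform, best-bit and weighted matching on identical splits
tab <- training_size_sweep(pop$gallery, k_values = c(2, 10), n_test = 6)
print(tab, digits = 3)
#>    k method    eer frr_at_far far_at_frr rank_one lowest_perfect_rank
#> 1  2  plain 0.0287     0.1141     0.0859     0.92                   3
#> 2  2   pbbm 0.0100     0.0699     0.0184     0.99                   2
#> 3  2    pwm 0.0100     0.0699     0.0184     0.99                   2
#> 4 10  plain 0.0287     0.1141     0.0859     0.92                   3
#> 5 10   pbbm 0.0000     0.0000     0.0000     1.00                   1
#> 6 10    pwm 0.0000     0.0000     0.0000     1.00                   1
```

Uniform Hamming matching misidentifies 8% of probes at rank one and sits
at ~2.9% EER regardless of training size (it learns nothing). Stability
weighting cuts the EER to 1% with only two training captures — where the
weights are still quantized to {0, 1} and coincide with best-bit masking
— and to zero here with ten, where the finer weight quantization
separates every probe.

```r
wm <- train_pwm(pop$gallery$classes$class001[1:10], "class001")
print(wm)
#> <weight_map> class 'class001': 256 bits, k_train = 10, operator 'synthetic'
#>  mean weight 0.3042, 40 bits at weight 1

probe <- pop$gallery$classes$class001[[11]]
weighted_similarity(pop$gallery$classes$class001[[12]], probe, wm)
#> [1] 0.7832563   # genuine: accept at any sensible threshold
```

Image galleries work the same way through `gallery_codes()` /
`cmd_train()` / `cmd_evaluate()`; `generate_vein_gallery()` renders
synthetic vein images so the full image pipeline (ROI → resample →
normalize → LBP/LLBP → match) can be exercised end to end.

## Command line

A thin dispatcher over the exported functions:

```sh
Rscript inst/cli/veinpwm.R simulate --out gallery --n-classes 6 --n-samples 8 --seed 1
Rscript inst/cli/veinpwm.R train    --gallery gallery --out templates --k-train 4
Rscript inst/cli/veinpwm.R match    --template templates/class001.pwm \
                                    --probe gallery/class001/005.png --threshold 0.6
Rscript inst/cli/veinpwm.R evaluate --gallery gallery --out results --k-train 4
```

(after installation, the script is at
`system.file("cli", "veinpwm.R", package = "veinpwm")`).

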