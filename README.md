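# lprseg

Semantic segmentation of rice canopy images into **background, leaf and
panicle** pixels, and quantification of the **leaf-to-panicle ratio (LPR)**
— a canopy trait that proxies how intercepted light is partitioned between
the source organ (leaf) and the sink organ (panicle) during grain filling.
Breeders and agronomists use LPR to compare genotypes and management
practices (nitrogen timing, growth regulators) from plain RGB photographs.

## The method

At the core is **FPN-Mask**, a fully convolutional feature-pyramid network:

- a residual backbone whose four stages C2–C5 are down-sampled at rates
  {1, 2, 4, 8} (the usual stride-4 stem and pre-C2 pooling are removed so
  thin leaf blades survive),
- a top-down pyramid with lateral 1×1 connections giving P2–P5 at the same
  rates (for a 256×256 input, P2 is 256×256 and P5 is 32×32),
- a fusion head that bilinearly up-samples P3–P5 to full resolution,
  refines each with a 1×1 convolution, concatenates them with P2, and maps
  through a 3×3 convolution (batch norm + ReLU) and a final 1×1 convolution
  to three output channels.

Training minimizes the multi-class **focal loss**

    L = mean over pixels of  -alpha_c (1 - p_c)^gamma log p_c

(γ = 2, α = inverse class pixel frequencies by default) with mini-batch 24
Adam at a base learning rate of 0.001. From a predicted mask, the trait is

    LPR = L / P

with L and P the leaf- and panicle-pixel counts. Group comparisons of LPR
use a Duncan-style shortest-significant-ranges test with a compact letter
display. Predictions can be corrected over **SLIC superpixels**
(S = 15, C = 0.2, N = 50) either interactively (region → class edit lists)
or by majority vote. Because no field dataset ships with the package, a
procedural **synthetic canopy generator** (curved tapered blades, granular
panicle clusters, soil mottle, shadows, GG/YG/YY stage color regimes)
provides images with exact ground-truth masks for training and testing
everything end to end. The network, its backpropagation and the Adam
optimizer are implemented inside the package (R + C++ kernels, BLAS
matrix multiplication); see the methods vignette
(`vignettes/lprseg-methods.Rmd`) for every modeling decision.

## Worked example

```r
library(lprseg)

## a synthetic grain-filling canopy with exact ground truth
cfg   <- scene_config(stage = "YG", seed = 7)
scene <- generate_scene(cfg)
compute_lpr(scene$mask, image_id = scene$image$id)
#>     image_id    L    P      lpr background_count
#> 1 scene_YG_7 2899 1799 1.611451            11686

## the scaled-down reference experiment: generate 200 + 50 scenes, train a
## reduced FPN-Mask (16 pyramid channels) on 64x64 crops for 30 epochs,
## evaluate on the 50 held-out scenes at full resolution (~12 min on 1 CPU)
bench <- synthetic_benchmark(seed = 1)
bench$metrics
#> Segmentation metrics (pooled over 819,200 pixels)
#>   pixel accuracy: 0.9801   mean IoU: 0.9315
#>   background acc 0.9776  IoU 0.9755  AUC 0.9989
#>   leaf       acc 0.9866  IoU 0.9090  AUC 0.9990
#>   panicle    acc 0.9955  IoU 0.9101  AUC 0.9998
#>   macro AUC: 0.9992

## compare LPR across groups with the shortest-significant-ranges test
recs <- bench$records
recs$half <- ifelse(seq_len(nrow(recs)) <= 25, "first", "second")
ssr_test(recs, "half")
```

`bench$metrics$per_class_accuracy` are per-class recalls on pooled test
pixels: with the default moderate color overlap and shadows, the reduced
model recovers panicle pixels at ≥ 0.99 and leaf pixels at ≥ 0.98, and the
one-vs-rest macro AUC exceeds 0.94. Each LPR record in `bench$records` has
the leaf count, panicle count, their ratio and the scene metadata.

A thin command-line wrapper covering the whole workflow
(generate / prepare / train / predict / refine / evaluate / lpr /
lpr-compare / run) ships in `inst/cli/lprseg.R`:

```sh
Rscript inst/cli/lprseg.R generate --n 50 --seed 1 --out data/
Rscript inst/cli/lprseg.R run --out run1/ --seed 1 --epochs 20
```

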