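# rpcseg

Pixel-level segmentation of **residual pancreatic cancer (RPC)** in H&E
regions of interest, with the full validation stack used to judge how such a
model transfers across slide scanners: leave-one-scanner-out
internal-external cross-validation and random-effects meta-analytic pooling
of per-scanner performance.

After neoadjuvant therapy, pathologists estimate how much viable tumor
remains in a pancreatic resection specimen. A segmentation model that labels
every pixel of an annotated ROI as background, normal ducts, cancer, other
epithelium or fat turns that estimate into a number — the count of
cancer-class pixels. This package implements the whole pipeline as reusable,
tested R:

- **Annotation handling** — 12-class taxonomy merged to 5 target classes
  (+ an ignore class excluded from loss and metrics), ASAP-dialect XML
  polygon parsing, scanline rasterization to label masks (pixel-center
  convention), PNG/CSV I/O.
- **Synthetic multi-scanner cohort** — a seeded generator of gland-like
  H&E scenes rendered by Beer-Lambert stain composition under four scanner
  color profiles, so every downstream stage is testable with known ground
  truth and no external data.
- **Balanced patch sampling** — 50%-overlap sliding window, inclusive 10%
  foreground-content threshold, 50-patches-per-class-per-case cap.
- **Stain operations** — Macenko-style deconvolution normalization onto a
  reference H&E basis (plus a Reinhard-style alternative), and
  rotation/flip/color-jitter augmentation.
- **Training** — a compact U-Net-style encoder-decoder (RcppArmadillo,
  hand-derived backprop), per-channel sigmoid + binary cross-entropy with
  ignore weighting, ADAM, case-level validation split, early stopping.
- **Stitched inference** — overlapping sliding window with raised-cosine
  weighted averaging, border-clamped anchors, exact conservation of
  agreeing scores.
- **Evaluation** — per-class pixel F1 (Dice), cancer-class headline score,
  per-scanner t-interval summaries.
- **Meta-analysis** — REML between-study variance tau², inverse-variance
  pooling, Hartung-Knapp-Sidik-Jonkman interval with a Jackson-type
  variance floor, I², Cochran's Q, Q-profile tau² CI; SE reconstruction
  from printed confidence intervals.

The pooled estimate is

> µ = Σ wᵢyᵢ / Σ wᵢ,  wᵢ = 1/(seᵢ² + τ²),  τ² by REML,
> CI: µ ± t₍k−₁₎ √(max(q, 1)/Σwᵢ),  q = Σ wᵢ(yᵢ−µ)²/(k−1)

## Worked example

Pool four per-scanner cross-validation summaries given as printed means and
95% CIs (the shipped file holds published per-scanner mean F1 tables from a
multicenter by-scanner cross-validation of RPC segmentation):

```r
library(rpcseg)
studies <- read.csv(system.file("extdata", "crossval_f1_printed.csv",
                                package = "rpcseg"))
main <- subset(studies, analysis == "main",
               select = c(label, effect, lower, upper))
meta_pool(main)
#> <meta_result> k = 4: pooled 0.7770 (95% CI 0.7105-0.8434)
#>   tau2 = 0.001093 [0.0000-0.0280], I2 = 75.1%, Q = 9.815
```

The pooled mean F1 across scanners is 0.78 with 95% CI 0.71–0.84 and
between-scanner variance τ² ≈ 0.001: performance is consistent enough to
summarize, with modest heterogeneity driven by the most divergent scanner.

End-to-end on the synthetic cohort:

```r
spec <- cohort_spec(n_cases = 8, roi_size = 192, seed = 1)
manifest <- generate_cohort(spec, default_scanner_profiles(), "cohort")
rois <- load_cohort(manifest, "cohort")
cfg <- train_config(base_channels = 8, lr = 5e-3, max_epochs = 10,
                    patience = 4, seed = 1)
cv <- run_crossval(rois, crossval_plan(manifest), patch_spec(128, 64), cfg)
crossval_table(cv)
#>           scanner_type n   mean_f1  ci_lower  ci_upper
#> philips        philips 8 0.9683313 0.9655121 0.9711505
#> hamamatsu    hamamatsu 8 0.9786547 0.9736006 0.9837088
#> 3dhistech    3dhistech 8 0.9407837 0.9308804 0.9506870
#> leica            leica 8 0.8382093 0.8185185 0.8579001
```

Each row is one leave-one-scanner-out fold: the model never saw that
scanner during training. The deliberately divergent 3dhistech and leica
profiles transfer worse — and retraining the 3dhistech fold *without* stain
normalization drops its mean F1 from 0.94 to 0.88, the package's
reproduction of the finding that normalization mainly protects the most
color-divergent scanner.

A thin CLI wraps the same functions: `inst/cli/rpcseg synth|crossval|pool`.

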