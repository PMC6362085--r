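# octmap

Unsupervised ordering of anterior-chamber OCT images in a 2-D plane.

## The problem

Assessing angle-closure glaucoma risk from anterior-segment OCT (AS-OCT)
normally requires an expert to annotate landmarks — most critically the
scleral spur, which is hard to locate in a substantial fraction of scans —
before geometric features such as the iridocorneal angle, the anterior
chamber depth and the angle recess area can be measured. `octmap`
implements a fully unsupervised alternative: it orders a whole database of
AS-OCT cross-sections in a two-dimensional plane using nothing but pairwise
image distances, so that clinically meaningful axes emerge without labels,
training, or landmark detection. The package targets researchers working on
automated anterior-segment image analysis.

## Method

Three stages, each exposed as ordinary R functions and as `octmap` CLI
subcommands:

1. **Pre-processing** (`preprocess_image()`): intensities are linearly
   rescaled to [0, 1]; the anisotropic raster is made isotropic by
   upsampling the coarse axis; a rectangular median filter
   (0.055 mm × 0.117 mm) and Perona–Malik anisotropic diffusion suppress
   speckle while keeping anatomical edges; the raw moments
   S = Σ M(i,j), X = Σ j M, Y = Σ i M, XX = Σ j²M, YY = Σ i²M, XY = Σ ijM
   give the centroid (Y/S, X/S) and intensity covariance COV, and the image
   is resampled into a zero-initialized canvas M⁽ᶜ⁾ twice its size with the
   centroid at the canvas center and the leading eigenvector v₁ of COV
   horizontal — removing the eye's in-plane pose.
2. **Pairwise distances** (`pairwise_distances()`): the Hellinger distance
   d_H = √(2 Σᵢⱼ (√(Mₗ⁽ᶜ⁾/Sₗ) − √(Mₘ⁽ᶜ⁾/Sₘ))²) on mass-normalized canvases
   (bounded by 2, invariant to global intensity rescaling), or the plain
   Euclidean distance d_E = √(Σ (Mₗ⁽ᶜ⁾ − Mₘ⁽ᶜ⁾)²).
3. **Embedding** (`isomap_embed()`, `tsne_embed()`): IsoMap or t-SNE run
   directly on the precomputed distance matrix yields mapped coordinates
   (w, v) per image; `residual_variance()` reports 1 − r² between original
   (geodesic) and embedded distances.

Validation utilities relate the map to clinical ground truth:
landmark-based features (`features_from_landmarks()`: chamber depth L,
angles α and β, ARA₅₀₀), the direction in the (w, v) plane maximizing the
correlation with a feature (`best_correlation_direction()`, closed form
√R² of the two-predictor least-squares fit), Image Map montages
(`render_image_map()`) and class-label overlays (`label_overlay()`). A
synthetic phantom generator (`generate_phantom()`, `generate_cohort()`)
produces AS-OCT-like images with known angle, depth and pose so the whole
pipeline is testable without clinical data.

## Worked example

Generate a 30-phantom cohort with apex angles uniform on [10°, 70°], run
the full pipeline, and ask how well the best direction in the map recovers
the ground-truth angle:

```r
library(octmap)

base <- phantom_params(width_px = 256L, height_px = 64L,
                       px_mm_x = 16 / 256, px_mm_y = 8 / 64)
cohort <- generate_cohort(30, angle_range = c(10, 70), seed = 7,
                          base_params = base)
imgs <- lapply(cohort, function(x) x$image)
names(imgs) <- sprintf("ph%02d", seq_along(imgs))
angle <- sapply(cohort, function(x) x$params$iridocorneal_angle_deg)

cfg <- pipeline_config(px_mm_x = 16 / 256, px_mm_y = 8 / 64, perplexity = 8)
man <- run_pipeline(imgs, cfg, features = data.frame(angle = angle))
man$correlations
#>   feature theta_deg          r     abs_r  n
#> 1   angle   36.8339 -0.9453401 0.9453401 30
```

The map's best direction explains the phantoms' iridocorneal angle with
|r| ≈ 0.95 (the sign and the direction θ are arbitrary under axis flips of
the embedding): the unsupervised ordering has rediscovered the clinically
decisive axis. `man$D` holds the 30 × 30 Hellinger matrix (435 pairs),
`man$embedding$coords` the (w, v) coordinates, and
`render_image_map(man$embedding, man$aligned, c(4, 8))` lays thumbnails on
a 4 × 8 grid so the ordering can be inspected visually.

## Command line

```sh
octmap phantom generate --n 100 --seed 7 --out phantoms/
octmap preprocess run --in phantoms/ --out aligned/ --config cfg.yaml
octmap distance compute --in aligned/ --metric hellinger --out D.csv
octmap embed run --dist D.csv --method tsne --out coords.csv
octmap evaluate correlate --coords coords.csv --features features.csv --out table.csv
octmap run --config cfg.yaml --in phantoms/ --out results/
```

(The `octmap` script is installed under `exec/` in the package library;
call it as `Rscript $(Rscript -e 'cat(system.file("exec/octmap", package="octmap"))')`
or add it to your PATH.)

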