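---
title: "Unsupervised ordering of anterior-chamber OCT images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised ordering of anterior-chamber OCT images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Angle-closure glaucoma risk is assessed from the geometry of the anterior
chamber: the iridocorneal angle, the anterior chamber depth, and the angle
recess area. These quantities are usually measured on anterior-segment OCT
(AS-OCT) cross-sections after an expert has located landmarks such as the
scleral spur — a landmark that is invisible or ambiguous in a substantial
fraction of clinical images. `octmap` implements a fully unsupervised
alternative: it orders a database of AS-OCT images in a two-dimensional
plane using only pairwise image distances, so that clinically meaningful
axes (angle, depth) emerge without any training labels or landmark
detection.

The pipeline has three stages.

1. **Pre-processing.** Each image is linearly rescaled to $[0, 1]$, the
   anisotropic raster is made isotropic by upsampling the coarse axis, a
   rectangular median filter and a Perona–Malik anisotropic diffusion pass
   suppress speckle while preserving the corneal and iris edges, and the
   image is centered and principal-axis-aligned into a zero-initialized
   canvas twice its size. With $M(i,j)$ the intensity $i$ pixels down and
   $j$ pixels right, the raw moments
   $S=\sum M$, $X=\sum jM$, $Y=\sum iM$, $XX=\sum j^2M$, $YY=\sum i^2M$,
   $XY=\sum ijM$ give the centroid $(Y/S,\,X/S)$ and the intensity
   covariance; the eigenvector $v_1$ of the largest covariance eigenvalue is
   rotated to the horizontal and the centroid to the canvas center. This
   removes the in-plane pose of the eye, which otherwise dominates
   inter-image distances.
2. **Pairwise distances.** For aligned canvases $M^{(C)}_l$ the package
   computes either the Hellinger distance
   $d_H = \sqrt{2\sum_{i,j}\left(\sqrt{M^{(C)}_l/S_l}-\sqrt{M^{(C)}_m/S_m}\right)^2}$
   (each image normalized by its total mass $S$, so $d_H \in [0,2]$ with 2
   exactly for disjoint supports, and invariant to global intensity
   rescaling) or the plain Euclidean distance
   $d_E = \sqrt{\sum (M^{(C)}_l - M^{(C)}_m)^2}$. All $n(n-1)/2$ unordered
   pairs are evaluated once.
3. **Embedding.** IsoMap (k-NN graph, shortest-path geodesics, classical
   MDS) or t-SNE is run *directly on the precomputed distance matrix* —
   never on re-extracted image features — producing mapped coordinates
   $(w, v)$ per image. The residual variance $1-r^2$ between the original
   (for IsoMap: geodesic) distances and the embedded Euclidean distances
   diagnoses how much structure the two dimensions capture.

Validation relates the map to clinical annotations: the landmark-derived
features (chamber depth $L$, iridocorneal angles $\alpha$, $\beta$,
$\mathrm{ARA}_{500}$), a best-correlating direction statistic in the
$(w,v)$ plane, an Image Map montage, and class-label overlays.

## The phantom generator

No clinical images ship with the package, so every stage is exercised on
synthetic anterior-chamber phantoms with known ground truth. A phantom is
built from analytic geometry in physical (mm) coordinates: a bright
corneal band between two concentric arcs (intensity 0.9, radius scaled
from a 7.8 mm outer curvature), two iris bands (0.7) whose top edges are
straight lines meeting the inner corneal arc's tangent at a prescribed
apex angle on each side, and a lens arc (0.5) whose apex sits a prescribed
chamber depth below the central inner corneal edge. The default canvas is
256 × 1024 px covering 8 mm × 16 mm (31.25 µm × 15.625 µm per pixel),
mirroring a Visante-style anterior-segment scan. The whole scene can be
rotated in-plane (the rotation is rigid in mm space even though the pixel
grid is anisotropic) and translated, and is corrupted by multiplicative
lognormal speckle $\exp(\sigma Z)$, $Z \sim N(0,1)$, with $\sigma = 0.5$
by default, plus additive uniform background noise on $[0, 0.05]$ —
values chosen to make the bands' intensity distributions clearly distinct
yet visibly noisy, as in coherent imaging. Because the rasterizer draws
exactly the analytic lines and arcs, ground-truth angles, depths, masks
and landmark sets are available to sub-degree/sub-pixel accuracy, and the
same seed always yields a bit-identical image.

What the phantoms do *not* emulate: A-scan physics, refraction at the
corneal interfaces, intraocular-lens artifacts, iris bowing, and the
long-tailed quality variation of clinical archives. Passing phantom tests
therefore demonstrates that the pipeline recovers geometry it can see
through stylized speckle — not that it is robust to every clinical
artifact.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| median window | 0.055 × 0.117 | mm (h × w) | counteracts the directional noise spreading introduced by upsampling the coarse axis; converted to the nearest odd pixel counts |
| diffusion `n_iter`, `kappa`, `lam` | 15, 0.1, 0.25 | –, intensity, – | explicit Perona–Malik scheme; `lam` at the 4-neighbor stability bound, `kappa` between speckle contrast and anatomical edge contrast on $[0,1]$ images |
| `isomap_k` | 12 | neighbors | standard neighborhood size; the k-NN graph must be connected (the package errors with component sizes otherwise) |
| `perplexity` | 30 (`tsne_embed`), 20 (pipeline) | – | t-SNE requires perplexity $< (n-1)/3$; 30 suits large databases, while the pipeline default 20 (≈ $n/5$ for 100-image cohorts) stays well inside the valid range and anchors global structure |
| `tsne_eta`, `tsne_exaggeration`, `tsne_exag_iter` | auto, 4, 250 | – | the automatic learning rate `max(n / (4 * exaggeration), 50)` avoids small-`n` divergence; gentle exaggeration favors a stable global arrangement over tight cluster separation |
| `tsne_restarts` | 5 | runs | non-convex objective; the lowest-KL map is kept (see below) |
| phantom speckle `sigma`, background | 0.5, 0.05 | –, intensity | strong but realistic multiplicative noise; background keeps no pixel exactly zero, as in real scans |

## Numerical choices

- **Index base.** Moments use 0-based pixel indices; centroid and
  covariance are translation-covariant, so the base only shifts the
  centroid consistently.
- **Eigenvector sign.** $v_1$ is defined up to sign; the package picks the
  sign with nonnegative horizontal component (nonnegative vertical on the
  pure-vertical tie), so alignment never mirrors an image left–right.
- **Resampling.** Rotation and centering compose into a single backward
  bilinear gather (one interpolation, zero fill); canvas pixels never
  touched by the source are exactly 0. Equal covariance eigenvalues make
  the rotation undefined — the identity is applied with a warning.
- **Homogenization direction.** The coarser axis is upsampled to the finer
  spacing (detail on the finer axis is preserved); pixel-center positions
  map endpoints to endpoints, preserving physical extent to within a pixel.
- **Median window rounding.** The mm window is converted per axis to the
  nearest odd pixel count, at least 1; a window of a single pixel in both
  axes degrades to the identity with a warning.
- **Hellinger mass.** $S$ is recomputed on the aligned canvas (resampling
  changes the source mass slightly), keeping $\sum M^{(C)}/S = 1$ exact so
  the disjoint-support bound of 2 is attained exactly.
- **t-SNE stability.** The t-SNE objective is non-convex, and on
  ~100-image cohorts single runs (of this implementation and of reference
  implementations alike) occasionally land in folded maps. The package
  (a) initializes from classical MDS of the input distances — a
  deterministic, globally informative start, (b) optionally restarts from
  seeded random configurations, and (c) keeps the map with the lowest
  Kullback–Leibler divergence, t-SNE's own loss. The selection never sees
  any ground-truth feature. With pipeline defaults the whole procedure is
  reproducible bit-for-bit from one seed.
- **Direction statistic.** The direction maximizing $|r|$ has the closed
  form of the two-predictor least-squares fit: $u^* \propto
  \Sigma^{-1}\mathrm{cov}(X, y)$ and $|r|_{\max} = \sqrt{R^2}$; the
  reported $r$ is the signed correlation at $\theta^* \in [0, \pi)$.
  Collinear coordinates fall back to the dominant principal axis.
- **Image Map assignment.** Grid cells are filled greedily in row-major
  order with the nearest unassigned image, ties broken by id order; a cell
  stays empty when no image lies within half a grid spacing
  (axis-normalized). Zero-extent coordinate ranges are expanded
  symmetrically so a degenerate cluster still renders in one cell.

## ARA500 construction

The angle-recess-area feature approximates both edges as lines: the inner
corneal edge through the scleral spur and the auxiliary corneal point, the
iris top edge through the two iris points. With $A$ their intersection
(the recess apex), $P$ the point on the corneal line 0.5 mm from the spur
on the side where the recess opens, and $Q$ the foot of the perpendicular
from $P$ onto the iris line, $\mathrm{ARA}_{500}$ is the area of triangle
$APQ$. The 500 µm offset is anchored at the scleral spur, the conventional
anchor for this feature. This is a deliberate line-based approximation of
the usual curvilinear definition: it is exact when both edges are straight
over the first 500 µm and degrades gracefully otherwise. Angles are
reported as the acute angle between the two lines, in $[0°, 90°]$.

## Problem sizes used by the tests and the acceptance script

Whole-cohort checks run on phantoms sampling the full 16 mm × 8 mm field
of view at a quarter of the native resolution (64 × 256 px, preserving
the 2:1 spacing anisotropy), a size at which a 100-image cohort — the
scale of the end-to-end angle-recovery checks — preprocesses, computes
4950 Hellinger distances, and embeds in well under a minute. Alignment
invariance is checked at the native 256 × 1024 resolution on noiseless
phantoms: a pixelwise correlation bound of 0.95 measures geometric
self-consistency up to interpolation losses, which per-pixel speckle
would mask regardless of alignment quality (resampling decorrelates
i.i.d. noise fields even under a perfect aligner). Cohort conditions for
the end-to-end checks are apex angles uniform on $[10°, 70°]$, chamber
depths uniform on $[2.5, 3.5]$ mm, pose jitter of $\pm 10°$ rotation and
$\pm 8$ px translation, and the default noise.

## Known limitations

- The t-SNE implementation is the exact $O(n^2)$ algorithm; it is meant
  for the hundreds-to-low-thousands regime of this application, not for
  $n \gg 10^4$.
- The phantom's iris top edge is a straight line, so landmark-derived
  angles are exact by construction; on clinical images the line
  approximation of a curved iris introduces annotator-dependent error the
  package cannot model.
- Dewarping/refraction correction and the rejection of zoomed or
  very-low-quality scans are out of scope; inputs are assumed to depict
  the whole anterior segment at a known pixel spacing.
- Embedding coordinates are defined up to rotation/reflection (IsoMap)
  and up to the optimizer's local minimum (t-SNE); only quantities
  invariant under these symmetries — correlations along the best
  direction, neighborhood structure, residual variance — are meaningful.
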