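---
title: "Convolutional species distribution models and their feature-space interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convolutional species distribution models and their feature-space interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(convSDM)
```

## The problem

Species distribution models (SDMs) relate presence-only occurrence records
to environmental predictors. Classical point-value SDMs (MaxEnt, random
forests on climate and soil vectors) see only the value of each predictor
at the occurrence location. A convolutional SDM instead consumes a
multi-channel *environmental tensor* — an image patch of remote-sensing
channels (RGB, near-IR, categorical land cover, elevation) centered on the
occurrence — and can therefore exploit spatial context: texture, landscape
configuration, and neighborhood statistics that no point value carries.

This package implements that pipeline end to end: tensor assembly from
raster layers, a multi-species convolutional classifier with an explicit
feature space, a point-environment random-forest baseline, a spatially
blocked evaluation protocol with species-balanced pseudo-absence AUC, and
an interpretation layer that embeds the learned feature space with
PCA + t-SNE and relates it to species traits, environment and geography.
Everything is exercised on a bundled synthetic-landscape generator with
known ground truth, so each claim the pipeline makes is testable without
any external download.

## The model

The classifier is a composition $z = \phi(x)$ of strided convolutional
blocks ending in global average pooling, with a linear species head
$\psi(z)$, trained by minimizing the cross-entropy of

$$\mathbb{P}(Y = k \mid X = x) \;=\; \sigma_k(\psi(z))
  \;=\; \frac{e^{\psi_k(z)}}{\sum_j e^{\psi_j(z)}},$$

so the outputs are *relative* probabilities of species given the location.
The feature vector $z$ is the interpretable object: species are roughly
linearly separable in it, and its low-dimensional t-SNE embedding is what
the interpretation modules visualize and regress.

The backbone is configurable (`convSDMConfig()`). The default is a small
desk-scale stack — 3 blocks of 3x3 convolutions (32, 64, 64 filters) with
ReLU, the first block at stride 1 and the rest at stride 2 — pooled
globally into $d = 128$ features, chosen so the full study runs in
minutes on one CPU core. A full-size architecture (e.g. an
Inception-style network with $d = 2048$) is a configuration, not a code
change: only the $\phi/\psi$ decomposition and the loss are fixed by
design.

Two defaults deserve their rationale. First, the *stride-1 first block*:
downsampling before any nonlinearity aliases fine texture, while a
stride-1 convolution can compute local differences that ReLU rectifies
into contrast energy for the deeper layers to aggregate. Second, the
*pooling*: plain global average pooling can in principle represent
neighborhood variability (mean of rectified high-pass responses), but it
has to learn that representation through the loss, which converges
slowly; the default `pooling = "avgsd"` therefore concatenates each
channel's spatial mean *and* spatial standard deviation over the final
map, exposing within-patch variability to the linear head directly. This
is the standard first-and-second-moment texture head; linear probes of
the terrain-roughness ground truth from the learned features roughly
double in $R^2$ with it, and the context-species results below depend on
it. `pooling = "avg"` restores plain average pooling.

Input encoding: the categorical land-cover channel is one-hot expanded at
the model input (stored tensors keep the integer class code); continuous
channels are standardized with statistics computed on the training split
only and stored with the model, to avoid leakage.

## The evaluation protocol

Ranks and top-k. For a test occurrence $i$, $r_i$ is the rank of its true
species in the descending score list. Ties are resolved *pessimistically*:
the true species is placed last among its ties, so a constant predictor
scores rank $S$, never rank 1. The pessimistic rule is a package decision
(the convention is otherwise underdetermined) and the brute-force oracles
in the tests use the same rule by explicit sorting.

$$A_k = \frac{1}{n}\sum_i \mathbf{1}[r_i \le k], \qquad
  SA_{k,s} = \frac{1}{j_s}\sum_{i \in s} \mathbf{1}[r_i \le k], \qquad
  MSA_k = \frac{1}{n_{sp}}\sum_s SA_{k,s}$$

$MSA_k$ is the unweighted mean over species with at least one test
occurrence; it prevents frequent species from dominating. At the reference
scale (20 species) the package reports $k = 5$; the conventional full-scale
choice is $k = 30$.

Spatial block holdout. Test occurrences are whole quadrats: the bounding
box is gridded (anchored at its lower-left corner, a package decision for
reproducibility), quadrats are drawn uniformly at random until the
cumulative occurrence count first reaches the target test fraction, and a
validation split (default 0.5%) is then drawn uniformly from the
remaining training occurrences. No quadrat ever mixes train and test.

Pseudo-absence AUC. Presence-only data has no absences, so pseudo-absences
for a species are drawn from *other* species' test occurrences in two
stages — species uniformly first, then an occurrence of that species
uniformly — which balances habitats across species rather than weighting
by occurrence counts. Each species receives 100 pseudo-absences, or as
many as its presences if it has more than 100. Draws are independent
(with replacement across draws); the two-stage recipe implies independent
draws, and the choice is documented so results are reproducible. The AUC
is the rank (Mann-Whitney) statistic with midranks; the convolutional
model is scored by its *logits* (a habitat-suitability index), the
baseline by its probabilities. MeanAUC is the unweighted species mean,
optionally per region.

## The synthetic landscape generator

The generator is first-class, tested code: it defines the study conditions
under which every end-to-end claim is verified.

- **Latent fields** on a 2 x 2 km grid at 2 m/px (defaults): a
  `temperature` field with a strictly monotone west-east gradient, a
  `moisture` field (seeded white noise convolved with a Gaussian kernel,
  60 m), and an `elevation` field built as a very smooth base (250 m
  kernel) plus fine relief (8 m kernel) whose amplitude is modulated by an
  independent smooth "ruggedness" field (150 m kernel). All fields are
  standardized; smoothing is periodic (FFT), which makes opposite borders
  correlate slightly — irrelevant at these kernel-to-extent ratios.
- **Channels**: land cover as equal-frequency threshold bands of a
  0.6/0.4 temperature-moisture mixture (4 classes by default); pseudo-RGB
  as per-class base colors plus continuous field modulation plus seeded
  noise (sd 0.05); near-IR as an affine moisture/class-reflectance mix;
  the elevation field as its own channel.
- **Species** (20 by default) are Gaussian niches. Non-context species
  have a narrow temperature optimum (sd 0.30, optima spread evenly along
  the gradient), a moderate moisture optimum (sd 0.60) and a wide
  elevation one (sd 1.20) — temperature is the primary axis, which is what
  the embedding-recovery check later exploits. Eight *context* species
  instead have a narrow niche (sd 0.25) on terrain roughness — the local
  standard deviation of elevation within 20 m — a neighborhood statistic.
- **Invisibility of the context statistic.** The coarse environment
  rasters handed to the point-value baseline are resampled from the
  *smooth elevation base only*, the way a coarse terrain or climate
  product would be; the fine relief exists only at imagery resolution in
  the elevation channel. Without this, the point elevation value is
  heteroskedastic in rough areas and leaks the neighborhood statistic to
  the baseline, which defeats the purpose of the contrast.
- **Sampling** is species-then-location: species by prevalence, location
  proportional to suitability times effort, restricted to a border margin
  of half a patch so patches never cross the world edge (this removes any
  padding policy at the source). Coordinates snap to pixel centers so
  patch extraction and truth lookup are exact. Effort is uniform by
  default; a "roadside" stripe option exists to probe citizen-science
  bias, but the bias model is an assumption — the sampling bias of real
  opportunistic data is not characterized here.

What the generator does *not* emulate: temporal dynamics, species
interactions, dispersal, geodesic geometry (a local planar CRS is
assumed), sensor artifacts, or label noise. Passing tests on this world
show the pipeline recovers structure it was designed to contain; they do
not certify performance on real imagery.

## Numerical and geometric conventions

- Pixels are half-open: pixel $(i, j)$ of a layer with resolution $r$
  covers $[x_{min} + (j-1)r,\; x_{min} + jr) \times
  (y_{max} - ir,\; y_{max} - (i-1)r]$, row 1 northmost, so every point
  belongs to exactly one pixel.
- For an even patch size $P$, the occurrence pixel sits at patch index
  $(P/2, P/2)$ (0-based); the patch covers $[c - rP/2,\, c + rP/2)$ on
  each axis. Patches crossing a layer border are an error — there is no
  implicit padding; occurrences too close to borders must be filtered
  upstream (the generator's margin guarantees it).
- Continuous layers resample bilinearly between pixel centers (clamped at
  the border, so output extrema never exceed the input's); categorical
  layers resample nearest-neighbor only, and requesting bilinear on a
  categorical layer is an error, not a warning.
- Rasters are stored as ESRI ASCII grids with a JSON sidecar for the
  layer kind — a plain-text, universally inspectable raster format.
- Suitability-map scaling: logits pass through a unit-slope sigmoid
  centered on the species' area-mean logit (computed over successful
  lattice points only), then min-max to $[0, 1]$. Any positive slope
  preserves order; 1 is the canonical choice. Constant inputs raise a
  degenerate-map error rather than producing an arbitrary surface.
- t-SNE: exact $O(n^2)$ gradient descent (perplexity 30, 500 iterations,
  learning rate 200, early exaggeration 12 for 100 iterations, seeded
  initialization) after optional PCA to 50 components. The settings are
  package defaults chosen for determinism and desk-scale n; they are not
  canonical values from elsewhere.
- Mosaic occupancy searches *within* each cell for the occurrence nearest
  the cell center (a per-cell search, not a global nearest-neighbor);
  geographic projection uses planar Euclidean 1-NN.

## Reference study scale and what it shows

The package's reference experiment (also what `scripts/acceptance.R`
reruns) is: 2 x 2 km world, 20 species (8 context), ~4,500 occurrences
split by 250 m quadrats into ~4,000 train (with a 0.5% validation draw)
and ~500 test (target test fraction 0.11, scaled up from the full-scale
2.5% so the test set keeps enough occurrences per species at n = 4,500),
32 px patches, the default backbone trained 16 epochs with Adam
(lr $10^{-3}$, batch 64) — 16 epochs is where the epoch-mean training
loss has roughly plateaued at this scale. On this study:

```{r, eval = FALSE}
world <- syntheticWorld(seed = 1)
occ <- occurrences(world)
split <- spatialBlockSplit(occ, quadratSize = 250, testFraction = 0.11,
                           valFraction = 0.005, seed = 2)
tensors <- assembleTensors(worldLayers(world), split, patchPx = 32)
tr <- split$split != "test"
model <- trainConvSDM(tensorSubset(tensors, tr), split$species_id[tr],
                      convSDMConfig(epochs = 12, seed = 3))
pred <- predictConvSDM(model, tensorSubset(tensors, !tr))
evaluateScores(pred$scores, split[!tr, ], k = 5, seed = 4)
```

the tests assert: species-mean top-5 accuracy well above the 0.25
random-ranking level; a context-species advantage of the convolutional
model over the point-value baseline; an embedding whose two t-SNE axes
recover the generating temperature value (OLS $R^2 \ge 0.3$); and
suitability maps that rank-correlate with the true niche surface
(Spearman $\rho \ge 0.4$). The exact numbers for a given seed come from
running the acceptance script; the vignette deliberately states none.

## Interpretation layer

`reduceFeatures()` embeds features (optional seeded subsample, PCA to 50,
t-SNE to 2-D or 3-D; the 3-D map variant conventionally skips PCA).
`buildMosaic()` discretizes the embedding for patch/trait/environment
mosaics; `bilinearEmbeddingColors()` + `geographicProjection()` paint the
embedding onto geography; `embedding3ToRGB()` turns a 3-D embedding into
a color map directly. `axisLinearModels()` fits OLS per embedding axis on
traits or environment, reporting estimates, standard errors, p-values
with star thresholds, $R^2$ and adjusted $R^2$; rows with missing
predictors are dropped and counted, and any environment predictor that is
an exact difference of two others is excluded automatically (the
exclusion is minimal — one column per dependency, preferring the
latest-declared column, matching the convention that derived variables
are declared after their components). These are deliberately plain
regressions: no spatial autocorrelation correction and no
multiple-testing adjustment beyond the stars, so p-values on spatially
autocorrelated data are optimistic and the models quantify linear
association with a nonlinear embedding — a lower bound on what the
feature space contains, not an effect-size estimate.

## Known limitations

- The synthetic world is stationary and noise-lean; real imagery has
  sensor artifacts, seasonal variation and label noise the generator does
  not model.
- The pseudo-absence AUC depends on the drawn pseudo-absences and on the
  extent of the study area; values are comparable between models
  evaluated on the same draw, not across studies.
- Exact t-SNE is $O(n^2)$ memory and time: fine for the tens of
  thousands of points the interpretation layer targets, unsuitable for
  millions.
- The per-epoch validation loss is logged for monitoring; the returned
  model is the final-epoch model (no early stopping).
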