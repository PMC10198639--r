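---
title: "Methods: connectivity-based sulcal parcellation and cross-species sulcal morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity-based sulcal parcellation and cross-species sulcal morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and design decisions
behind `sulcparc`. It is the authoritative account of *why* the package
computes what it computes; the README shows *how* to run it.

## 1. The scientific setting

Two procedures are implemented. The first asks whether the voxels of a
sulcal region of interest (ROI) — prototypically the macaque principal
sulcus — fall into distinct subregions according to their resting-state
connectivity with the rest of the brain, and how many. The second
quantifies sulcal morphology across four primate species (human,
chimpanzee, baboon, macaque): where sulcal features sit along the
anteroposterior (Y) axis relative to subcortical landmarks once brain
size is normalized out, how often sulci and junction patterns occur, and
whether occurrence differs by species.

Since no public dataset accompanies these analyses, the package treats
the synthetic-data generator as part of the scientific contract: its
defaults *are* the study conditions, and the tests demonstrate that the
machinery recovers known planted structure under those conditions.

## 2. Synthetic fMRI phantom

`phantomConfig()` defaults encode the acquisition: TR 1.8 s, 400 volumes
per run, 12 runs, 1.8 mm isotropic voxels on a 24 × 28 × 20 grid. The
phantom lays out an elongated ~200-voxel ROI strip along world Y inside a
gray-matter slab, disjoint WM and CSF blocks, and one gray-matter
"target network" block per ROI zone. The affine maps voxel centers to mm
with the grid centered at the world origin; world Y increases rostrally.

Zone boundaries split the ROI into contiguous caudo-rostral zones. The
study preset places them at the macaque genu-rostral and
CGS/SUROS/SOS-junction levels of the synthetic landmark table (Section
5), mirroring the observation that functional cluster borders coincide
with anatomical landmarks.

Signal model, per run:

* each zone's latent time course is a sum of six sinusoids with
  frequencies drawn uniformly in [0.01, 0.1] Hz, random phases and
  amplitudes, standardized to SD 1. Sinusoid sums guarantee in-band
  energy, so the band-pass stage is non-destructive by construction;
* the zone signal (SD `signalSd`, default 1) is added to the zone's ROI
  voxels and to its dedicated target network;
* all voxels receive AR(1) noise (`ar1` = 0.3, stationary SD `noiseSd` =
  1), a baseline of 100, and artifacts: 0.5 × noiseSd each of a CSF
  drift, a WM drift and a standardized motion-coupled component; WM and
  CSF compartments additionally carry 2 × noiseSd copies of their drifts
  so nuisance regression has real work to do;
* motion parameters are six independent Gaussian random walks (step SD
  0.02).

Defaults give a planted voxel-to-target correlation near 0.5 before
smoothing — strong but not caricatural. What the phantom does *not*
emulate: realistic anatomy and registration error, field inhomogeneity,
physiological noise spectra, behaviorally modulated activity. Passing
tests therefore certify the algorithmic chain, not performance on real
acquisitions.

Reproducibility: one master seed drives everything. Per-run seeds are
drawn from a seeded RNG (not arithmetic on the seed), so run substreams
are independent and the same seed reproduces every artifact
bit-identically.

## 3. Preprocessing

Fixed stage order: band-pass → nuisance regression → smoothing.

* **Band-pass** 0.01–0.1 Hz. The filter family is a design choice (the
  procedure is specified only by its band): order-2 Butterworth applied
  forward–backward, i.e. zero-phase, so that temporal features are not
  shifted relative to each other before correlation. The implementation
  uses steady-state initial conditions and odd reflection padding
  (`filtfilt` semantics), which removes DC exactly up to numerical noise;
  contracts tested: DC attenuation below 1e−6, 0.05 Hz amplitude
  retention ≥ 0.9, ≥ 90% attenuation at 2.2× the upper edge.
* **Nuisance regression**: OLS residuals against an intercept plus eight
  confounds (six motion parameters, mean CSF, mean WM). The intercept is
  included as standard practice so residuals are mean-zero. Rank-deficient
  confound matrices drop dependent columns with a warning. Residual
  orthogonality to every confound is tested at 1e−8 (relative).
* **Smoothing**: separable Gaussian, FWHM 4 mm, σ = FWHM/(2√(2 ln 2))
  converted to voxels per axis; FWHM 0 is the identity. No mask-based
  renormalization is applied (matching common neuroimaging-tool
  behavior); at grid edges the truncated kernel is renormalized so
  constant images pass through exactly — tests that measure the impulse
  FWHM use interior voxels.

## 4. Fingerprints and spectral parcellation

* **Targets** are gray-matter voxels *minus* the ROI. Including ROI
  voxels would let trivial self- and neighbour-correlations dominate the
  row similarity; the choice is configurable
  (`fingerprintMatrix(includeRoiTargets = TRUE)`).
* **Fisher z**: r is clipped to ±(1 − 1e−7) before `atanh`, which is
  undefined at |r| = 1; zero-variance voxels contribute r = 0 so
  degenerate time courses never poison the matrix.
* **Similarity**: Pearson correlation between fingerprint rows; constant
  rows get similarity 0 (logged).
* **Graph**: per row, keep the `kNN` largest off-diagonal similarities,
  floor negatives at 0 (Laplacian theory needs nonnegative weights),
  symmetrize by elementwise max, zero the diagonal. Default
  `kNN = max(10, ⌈log2 n⌉ + 1)` — no neighbour count is prescribed by the
  procedure, so a standard connectivity-guaranteeing heuristic is used.
* **Embedding**: symmetric normalized Laplacian with row-normalized
  eigenvectors (Ng–Jordan–Weiss), the robust standard for k-NN graphs.
  The clustering acts on the eigen*vector* matrix (the only sensible
  reading of clustering "on the eigenvalues matrix"). Isolated vertices
  get a zero embedding row and are flagged rather than producing NaNs;
  disconnected graphs trigger a warning and are handled naturally (one
  zero eigenvalue per component).
* **K-means**: k-means++ seeding, 50 restarts, fixed seed; the restart
  with the lowest within-cluster sum of squares wins. Determinism under a
  fixed seed is tested.
* **Scores**: the silhouette (mean over points of (b−a)/max(a,b);
  singleton clusters contribute 0) *and* the variance ratio
  (between-/within-cluster sums of squared distances). The verbal
  description of the selection score in the source analysis matches the
  variance ratio, while its name ("silhouette index") matches the
  silhouette; both are computed and reported side by side, and the
  silhouette drives selection by default. Scores are computed in the
  spectral embedding — the space K-means actually clusters — with the
  fingerprint-row space available via `selectK(scoreSpace =
  "fingerprint")`.
* **Model selection**: k is scanned over 2..7. A one-cluster solution is
  not evaluable under the silhouette, so the scan starts at 2. The chosen
  k maximizes the mean silhouette across seeds; exact ties break toward
  the smallest k.
* **Cross-run maps**: per-run labelings for probability maps are computed
  at the globally (modal) selected k so all runs share one label space.
  Alignment to the first run maximizes contingency-table overlap; with
  k ≤ 8 the exhaustive search over k! permutations is exact (and
  equivalent to the Hungarian assignment). Clusters are renumbered
  caudo-rostrally by mean world Y (ties: cluster size, then lowest
  original label), and per-voxel cluster frequencies across runs form the
  probability map.

## 5. Sulcal tables and landmarks

The landmark vocabulary is fixed: mammillary-body rostral limit, anterior
commissure, optic-chiasma rostral limit, genu caudal/rostral limits,
rostrum caudal limit, CGS/SUROS/SOS junction. No numeric landmark table
is published for the real anatomies, so `landmarkSet()` places landmarks
at fixed caudo-rostral *fractions* of each species' anteroposterior
extent (−0.35, −0.25, −0.18, −0.12, −0.06, 0, 0.15 of 175/110/85/60 mm).
These synthetic levels preserve the ordering and per-species scaling that
the normalization arithmetic needs.

`simulateSulcalTables()` draws, per (subject, hemisphere, sulcus),
presence as Bernoulli with the species' probability; present features get
caudal Y = anchor-landmark Y + N(0, jitter) with jitter SD 2% of the
extent, and a rostral Y extending rostrally. Junction patterns are
Bernoulli rows without coordinates. The study preset uses 80 subjects ×
2 hemispheres per species; junction gradients that are printed in the
source results (PMFS-P detached from IPRS-S: 54/34/3/0%; SPR-S joins
SFS-P: 99/99/19/4%) are used as generating probabilities, remaining
presence probabilities are synthetic. Note the generator draws
hemispheres independently — there is no true subject random effect — so
the mixed model's variance component is genuinely 0 under the preset;
this is deliberate, as it exercises the documented fallback.

## 6. Morphometry statistics

* **Normalized distance**: (y_feature − y_landmark)/extent. Missing Y
  (absent sulcus) propagates as NA; absent sulci count toward occurrence
  frequencies but never toward distance medians.
* **Landmark assignment**: per candidate landmark, the median normalized
  distance across records (hemispheres pooled — whether medians were
  taken per subject or pooled is not specified upstream; pooling is the
  default and the records you pass define the pool). Medians use the
  lower-median convention for even counts, so results are deterministic.
  The assigned landmark minimizes |median|; exact ties are flagged and
  resolved to the most caudal candidate.
* **Species test**: likelihood-ratio chi-square between
  `presence ~ species + (1 | subject)` and the intercept-plus-random-
  intercept null, numerator df = n_species − 1. An F statistic with a
  Satterthwaite-style denominator df is *not* reported: denominator-df
  approximations for binomial GLMMs are software-specific and not
  reproducible from a methods description, so DenDF is "n/a" and the
  method tag records the route taken. When the random-effect variance
  hits its 0 bound the model degenerates to ordinary logistic regression
  (message); when a species sits at exactly 0% or 100% presence the ML
  estimate diverges (separation), and a bias-reduced Firth fit with a
  penalized LRT is used instead (warning).
* **Post hoc**: all pairwise species contrasts on the logit scale, Wald z
  tests, Holm adjustment. Holm over Tukey's multivariate-t because the
  latter is not well defined across this family of fits (GLMM / glm /
  Firth) while Holm is assumption-light and conservative; family-wise
  error control is verified by simulation.

## 7. Problem sizes used by the test suite

Chosen as the package's own desk-scale study conditions:

* parcel-count selection: the full preset (12 runs × 400 volumes,
  198-voxel ROI, k = 2..7, 5 seeds);
* planted-zone recovery: 10 phantom seeds, one 400-volume run each,
  median adjusted Rand index ≥ 0.9 required;
* landmark-assignment recovery: 500 simulations, 20 records each, jitter
  SD = 1/5 of the 10-mm candidate spacing, ≥ 95% recovery required;
* presence-frequency coverage: 500 seeds of Binomial(160, 0.54) against
  the exact central 95% interval;
* statistical calibration: 500 null replicates of 4 species × 30
  subjects × 2 hemispheres; species-test type-I error within 0.05 ± 0.02
  and post hoc family-wise error ≤ 0.07.

Unit tests additionally pin every operation to an independent oracle:
brute-force correlation and silhouette implementations, exhaustive
normalized-cut search on 10-node graphs, exhaustive permutation search
for label alignment, closed-form OLS identities, and FFT-based filtering.

## 8. Known limitations

* The phantom's planted zones are closer to block-structured than real
  connectivity gradients; silhouettes near 1 on the preset reflect that
  idealization, and only the *selected k* (not the silhouette magnitude)
  should be compared with real-data analyses.
* The species-test statistic is a chi-square, not the F reported by
  mixed-model software with denominator-df approximations; p-values agree
  closely in large samples but are not numerically identical.
* Landmark Y levels are synthetic fractions; analyses of real data should
  supply a measured `LandmarkSet` via `readLandmarks()`.
* Exhaustive label alignment is exact but limited to k ≤ 8, which covers
  the scanned range k ≤ 7.
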