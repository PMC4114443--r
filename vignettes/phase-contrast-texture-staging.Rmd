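---
title: "Methods: simulated in-line phase-contrast imaging and GLCM texture staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated in-line phase-contrast imaging and GLCM texture staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In-line (propagation-based) X-ray phase-contrast imaging exploits the fact
that for soft tissue at hard-X-ray energies the phase decrement of the
complex refractive index, $n = 1 - \delta - i\beta$, exceeds the absorption
index by roughly three orders of magnitude. A coherent beam that traverses
a specimen accumulates phase $\phi = -\tfrac{2\pi}{\lambda}\int \delta\,dz$
and amplitude attenuation $\exp(-\tfrac{2\pi}{\lambda}\int \beta\,dz)$;
after free-space propagation the phase gradients interfere into measurable
intensity fringes, which outline tissue boundaries far more sharply than
absorption alone. Stomach specimens carrying progressively developed
implanted tumours show, in such projective images, two monotone trends:
thickening of the gastric wall and coarsening of the wall texture. This
package implements the complete analysis chain that quantifies those
trends — texture statistics on random regions of interest, a
principal-component discriminant, and a cross-validated stage classifier —
together with a physics-based simulator that supplies ground-truth input
images, since no public image data exist for this kind of experiment.

# The synthetic specimen generator

`make_stage_phantom()` builds a two-dimensional cross-section of an
air-filled stomach-like organ: an annular tissue wall with a perturbed
outer boundary (low-order angular harmonics), an air lumen, and — from the
day-5 stage on — hyperplasic nodules bulging from the inner wall. Tissue
$\delta$ is modulated by a stationary Gaussian random field whose
amplitude and correlation length are stage-dependent; $\beta$ is a fixed
fraction of $\delta$ so the tissue $\delta/\beta$ ratio (~700) matches the
soft-tissue regime. The optical constants are order-of-magnitude choices
(water-like electron density $3.34\times10^{29}\,$m$^{-3}$, $\beta$ chosen
so $\mu \approx 250\,$m$^{-1}$ at 13 keV); no quantitative $\delta,\beta$
tabulation exists for gastric wall or tumour at this geometry, and the
values live in configuration, not code.

Two imaging geometries are derived from one phantom:

* **slice** — the per-pixel $\delta,\beta$ grids are treated as a
  tomographic cross-section; in-plane line integrals along rotated rays
  give one detector row per angle (sinograms, CT);
* **screen** — the organ is treated as a closed shell seen en face; the
  through-beam tissue chord at in-plane radius $r$ is
  $2(\sqrt{R_{out}^2-r^2} - \sqrt{R_{in}^2-r^2})$, nonzero over the whole
  silhouette and longest at the rim (which renders the familiar bright
  rim ring), and the stage texture modulates this tissue column
  everywhere. The chord map is smoothed by a 1.2 px Gaussian because the
  ideal shell has a derivative singularity at the inner tangent radius
  that no real organ surface possesses.

## Stage parameter table

| stage  | wall (µm) | texture amplitude | correlation length (µm) | nodules |
|--------|-----------|-------------------|--------------------------|---------|
| normal | 72        | 0.040             | 27.0                     | 0 |
| d3     | 100       | 0.055             | 24.0                     | 0 |
| d5     | 135       | 0.070             | 21.5                     | 2 |
| d7     | 170       | 0.085             | 19.0                     | 4 |
| d9     | 205       | 0.105             | 16.0                     | 7 |
| d11    | 240       | 0.125             | 13.5                     | 10 |

Wall thickness and texture amplitude are nondecreasing by construction —
that is the disease progression the generator emulates. The amplitudes
were calibrated from the imaging physics rather than picked freely: the
phase modulation a texture of relative amplitude $a$ imposes on the
projected column is $\sigma_\phi = \tfrac{2\pi}{\lambda}\delta\,a\,c$
(with $c$ the tissue chord), and its intensity contrast after propagating
$z$ scales like $\pi\lambda z/(2\ell)^2$ per radian for texture of scale
$\ell$. The table keeps $\sigma_\phi$ between ~0.5 rad (normal) and
~5 rad (d11): below that range the texture disappears under the 8-bit
quantization; far above it the phase speckle is fully developed and its
statistics stop responding to stage. Both failure modes would break the
monotone feature response that is the generator's contract.

What the generator does **not** emulate: real gastric anatomy (rugae,
layered wall), histology-driven texture, partial coherence of the source,
detector blur, formalin-fixation artifacts. Passing tests on these
phantoms therefore demonstrate that the analysis chain responds correctly
to controlled monotone structure — not that the specific published
threshold values transfer to real specimens.

# Forward imaging model

`transmit()` applies the projection approximation; the exit field is
$\exp(-i\tfrac{2\pi}{\lambda}\int\delta\,dz)\exp(-\tfrac{2\pi}{\lambda}\int\beta\,dz)$
under unit plane-wave illumination (the 59 m source distance of the
emulated beamline justifies ignoring magnification and partial
coherence). `fresnel_propagate()` uses the exact angular-spectrum
transfer function $\exp(i\tfrac{2\pi}{\lambda}z\sqrt{1-(\lambda f)^2})$ —
non-paraxial, unitary on the propagating band, hence energy-conserving to
machine precision; evanescent components are suppressed, negative $z$
back-propagates, and $|z|$ beyond the sampling bound $N\Delta x^2/\lambda$
raises an advisory error. `acquire_projection()` scales intensity to the
expected photon count (default $10^4$/pixel), draws Poisson noise under an
explicit seed, and quantizes linearly to 8 bits.

Quantization is the one step with a genuine choice: per-image min–max
(default, mirrors autoscaled detector output) versus a fixed reference
window. Texture features depend on it, so the mode is recorded in every
image's metadata. The staging study uses the fixed window $[0, 2.5]$
(relative to the empty beam) with inverted, attenuation-bright display —
the radiographic convention in which a thicker wall is brighter — because
cross-image comparability of gray levels is exactly what a cross-stage
texture comparison needs.

# CT reconstruction

`fbp_reconstruct()` implements parallel-beam filtered back projection:
band-limited ramp kernel assembled in the spatial domain, apodization by
Ram-Lak (none), Shepp-Logan, or Hann windows, frequency-domain filtering
of each row, and bilinearly interpolated backprojection normalized by
$\pi/N_{angles}$. Intensities are first converted to line integrals by
`neglog()` (non-positive bins are floored to one quantization level, with
a reported count). Values outside the inscribed circle are masked to zero:
the circular streaks outside it are a known artifact of the method, and
masking keeps them out of any downstream texture region. On the analytic
disk oracle (180 angles, 256 detector bins) the in-disk mean is recovered
to 0.04% and the global RMSE is ~3% of the dynamic range. Whether the
published workflow log-transformed its projections before reconstruction
is not recoverable; both paths are exposed (`neglog` on by default in the
pipeline configuration).

# Texture features

`compute_glcm()` quantizes the 8-bit range linearly into $K$ levels
(default $K = 16$; a 50×50 ROI provides ~2500 pixel pairs, far too few to
populate a 256×256 co-occurrence matrix), counts co-occurring pairs at
distance 1 along the four standard directions, symmetrizes, pools the
offsets and normalizes. Nine Haralick statistics follow: angular second
moment, inertia, inverse difference moment, entropy, correlation, sum
average, difference average, sum entropy, difference entropy. Conventions,
each of which some published formulations leave open:

* logarithms are base 2 (entropies in bits); any fixed base only rescales
  entropies consistently;
* the difference marginal sums over $|i-j| = k$, which makes it a proper
  probability distribution on a symmetric GLCM (summing the signed
  difference over $k \ge 0$ would drop half the mass);
* a constant ROI has zero marginal variance; its correlation is defined
  as 0 with a warning rather than an error, so random ROI sampling cannot
  abort a run;
* ROI coordinates are 0-based, row-major, spans half-open; placement is
  uniform over all mask-contained positions without corner replacement,
  overlap permitted.

The ROI sampling mask shipped with the phantoms is the specimen
silhouette eroded by a small margin (8 px minimum, 5% of the image side).
Sampling across the organ border would let the border's own — stage
independent — edge fringes dominate every ROI statistics alike; the
eroded mask makes the features measure wall texture, which is the
quantity of interest.

# PCA discriminant

Per specimen, the 20×9 feature matrix is standardized (mean 0, unit
sample SD, denominator $n-1$), its 9×9 Pearson correlation matrix is
eigendecomposed, and components are retained by the cumulative
contribution rate rule (smallest $m$ with CCR > 80%). Per-ROI scores are
the loadings applied to the feature rows; the region discriminant is the
mean of $F_1 + F_2$ against a threshold (8.5 in the original data's
scale), with the boundary value assigned to the cancer class — a
screening rule favours sensitivity.

Two genuinely open design points and how they are resolved:

* **Raw versus standardized scores.** Applied to standardized features,
  per-specimen scores have mean exactly 0 for every specimen — centring
  removes all between-specimen information, so a per-specimen mean table
  can only be non-trivial on the raw path. `pca_report()` defaults to
  standardized scores (the statistically clean choice for a single
  specimen); the pipeline's per-specimen summary table uses the raw path,
  and the cross-stage comparison pools all 120 ROIs into one standardized
  frame first (`pooled_stage_scores()`), which is the only frame in which
  scores of different specimens are commensurable.
* **Eigenvector orientation.** Eigenvector signs are mathematically
  arbitrary but flip the meaning of any score threshold.
  `eigendecompose()` fixes signs by a non-negative loading sum (tie:
  largest-magnitude loading positive), a neutral algebraic convention
  used by its unit tests. The discriminant layer instead orients each
  component so its loading on angular second moment — the canonical
  uniformity feature — is non-negative (`orient_uniformity()`): positive
  scores then mean regular texture, and normal mucosa scores above
  cancerous tissue, which is the direction the discriminant is meant to
  encode. Under a loading-sum convention the first component of pooled
  texture data aligns with *heterogeneity* (six of the nine features grow
  with textural disorder), which would silently invert the rule. The
  absolute threshold 8.5 is tied to the scale of the data it was derived
  from and is a configuration parameter, not a constant of nature.

# Staging classifier

The 120-sample dataset (6 stages × 20 ROIs × 9 features, provenance
checked for duplicate corners) is classified by a one-vs-one linear-kernel
SVM (cost $C = 1$, an established convex solver underneath) under plain —
unstratified — 10-fold cross-validation: folds of 12 test / 108 training
samples, every ROI tested exactly once, features standardized by
training-fold statistics inside each fold to avoid leakage. The ROI (not
the specimen) is the cross-validation unit; ROIs from one image are
statistically dependent, so fold accuracies are optimistic in exactly the
way the original protocol's arithmetic implies — a caveat, not a bug, and
flagged here deliberately. Mean accuracy is compared against the 1/6
chance level with an exact binomial test, and a label-permutation control
verifies collapse to chance.

# Problem sizes and numerical tolerances

The shipped study conditions are 256×256 phantoms, one projective image
per stage, 20 ROIs of 50×50 px per image, 180-angle sinograms for the CT
branch; the whole chain runs in seconds. Key numeric contracts, each
asserted by a test: GLCM equals exhaustive pair enumeration on all 512
3×3 binary images exactly; eigen-reconstruction of the correlation matrix
to $10^{-8}$; score variances equal eigenvalues to $10^{-6}$; energy
conservation of pure-phase propagation to $10^{-6}$ relative; forward/
inverse propagation reciprocity to $10^{-8}$ RMS; analytic-disk FBP RMSE
below 5% of the dynamic range with error non-increasing in the number of
angles.

# Known limitations

The phantoms are stylized; none of the published absolute values (the
per-specimen $F_1+F_2$ means, the 8.5 threshold, the 83.3% accuracy)
can be reproduced without the original specimen images, which were never
deposited — only structural counts, spectral identities, physical limits
and the *directions* of the texture and discriminant trends are
reproducible claims, and those are what the test suite asserts. Phase
retrieval, polychromatic spectra, detector point-spread, iterative
reconstruction and anatomically faithful organ models are out of scope.
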