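---
title: "Unmixing multimodal images with incomplete multisets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unmixing multimodal images with incomplete multisets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcrfuse)
```

## The model and its assumptions

Every hyperspectral image in `mcrfuse` is treated, after unfolding pixels
into rows, as an instance of the bilinear mixing model `D = C Sᵀ + E`: each
pixel spectrum is a non-negative combination of a small number of pure
constituent signatures. The assumptions that carry the whole analysis are

* **bilinearity** — signal contributions add linearly across constituents
  (true for fluorescence emission and, after baseline removal, a good
  approximation for Raman scattering);
* **shared signatures** — a constituent has one spectral signature per
  modality, identical across all images of the set (instrument drift and
  matrix effects are not modelled);
* **shared constituents** — images concatenated into one multiset are
  explained by one common component basis. Components may be *absent* from
  individual images; that is a constraint, not a model change.

A multiset is a single matrix built by concatenating unfolded images
row-wise (same pixels, different channels) and/or column-wise (same
channels, different pixels). When scanned areas or pixel sizes differ
between modalities, some (row block × column block) cells were simply never
measured. `multiset_matrix` stores this as an explicit logical mask —
missing cells are never represented by sentinel numbers, so no arithmetic
can silently absorb them — and requires block-constant missingness with at
least one observed cell per row and column block.

The incomplete-multiset solver (`run_incomplete_mcr`) keeps the classical
MCR-ALS structure but computes each concentration row from the observed
channels of that row only, and each spectral column from the observed rows
of that column only. Missing blocks therefore contribute nothing to the
fit; they can be *predicted* afterwards from the fitted factors
(`predict_missing_blocks`), which is exactly how whole-cell maps and
complementary-modality signal are extrapolated beyond the jointly scanned
core. Rows sharing an observation pattern are solved in one batched
factorization; block-wise missingness guarantees there are only a few
patterns, and the result is identical to the row-by-row definition (the
test suite verifies this against an independent QR solver on random masked
systems).

### Identifiability and the undetermined flag

A component with zero signal over every observed channel of a row block
(e.g. a non-fluorescent constituent inside a fluorescence-only image) is
structurally invisible there: any coefficient value would leave the fit
unchanged. The solver sets those coefficients to zero and flags them in
`undetermined` (row block × component) rather than failing or inventing
values. Recovery scores in `evaluate_recovery` exclude flagged entries.
Note the asymmetry: the *Raman spectrum* of such a component is still
recovered (from the fused core and Raman-only blocks), and its *predicted*
fluorescence block is still meaningful because its fluorescence signature
is constrained to zero.

## Fit metrics

Fit quality is the lack of fit `LOF(%) = 100·sqrt(Σe²/Σd²)` and the
explained variance `100·(1 − Σe²/Σd²)`, with both sums restricted to
observed entries. The square-root form is the standard convention and is
the only one consistent with the pairing of the two metrics (a model with
16 % LOF explains 97.44 ≈ 97 % of the variance; 10 % LOF explains 99 %);
`fit_metrics` enforces `var = 100·(1 − (LOF/100)²)` by construction.
Metrics are reported overall and per row block; convergence is judged on
the overall LOF (default: stop when its relative change drops below 0.1 %,
cap at 100 iterations — the criterion type is standard, the values are this
package's defaults).

## Constraints

* **Non-negativity** on `C` and `Sᵀ`. Default mode `"nnls"` solves each
  row/column as a true non-negative least-squares problem (block principal
  pivoting over the normal equations, columns grouped by passive set —
  `nnls_multi`), which is the least-squares-consistent interpretation;
  `"clip"` (zero out negatives after an unconstrained solve) is available
  where speed matters more than exactness.
* **Correspondence of species**: `zero_C_blocks` pairs `(row block,
  component)` force a component's concentration to exact zero in images
  where it is known absent. Internally the component is *excluded from the
  solve* for those rows, not zeroed afterwards, so the remaining
  coefficients stay least-squares optimal.
* **Equality-to-zero spectral segments**: `zero_S_segments` pairs
  `(component, column block)` do the same on the spectral side, e.g. null
  fluorescence signal for non-fluorescent constituents. A component may not
  be zeroed in every column block.

After each spectral update every component is rescaled to unit Euclidean
norm over its full concatenated spectrum, with the inverse factor absorbed
into `C`. This resolves the intrinsic scale ambiguity of the bilinear model
without changing the reconstruction `C Sᵀ` (asserted to 1e-10 in the
tests). Normalizing per-modality segments instead would fight the
data-driven relative scaling of the two modalities, so the full augmented
spectrum is used.

## Initial estimates

`simplisma_initial_spectra` selects the `n` purest pixel spectra: purity is
`sd/(mean + α·max(mean))` with a determinant-based independence reweighting
against already-selected rows, deterministic by construction. The noise
fraction default `α = 0.05` is this package's choice. For the fusion
pipeline, however, the default initialization follows the two-stage route:
complete-data MCR runs on the fluorescence-only and Raman-only multisets,
component pairing across modalities through the correlation of their
fused-core distribution maps (solved exactly over all assignments), and
concatenation of the paired pure spectra — unpaired Raman components start
with, and are constrained to, zero fluorescence segments.

## Preprocessing chain

Applied to Raman cubes before analysis (`preprocess_raman`), each step with
its parameters in `preprocess_config`:

* **Cosmic spike removal** — the stated rule is only the *replacement*
  (interpolation from the nearest spectral channels); detection is this
  package's design: deviation from a running median (window 7) beyond 8
  robust standard deviations. Because a running median passes exactly
  through the centre sample on monotone stretches, the robust scale is
  taken from the nonzero deviations; in the exactly noiseless limit any
  departure from the running median is treated as a spike. The operation is
  idempotent on its own output.
* **SVD–Fourier denoising** — rank-truncated SVD with hard Fourier low-pass
  filtering (cutoff × Nyquist) of the retained right singular vectors.
  Rank 10 and cutoff 0.5 are exposed defaults, not prescribed values;
  cutoff 1 reduces exactly to truncated SVD.
* **AsLS baseline** — Whittaker-style smoother with asymmetric weights
  (`λ = 1e5`, `p = 0.001`, 10 iterations, second-difference penalty; the
  standard settings), applied per pixel (per-pixel vs per-image application
  is unstated upstream; per pixel preserves pixel-specific background).
  Subtracting the baseline estimate yields the corrected spectrum.
* **Range selection** — 640–1750 cm⁻¹, inclusive on both ends.
* **Spatial binning** (`bin_spatial`) — adjacent pixel spectra are *summed*
  (not averaged), remainder pixels dropped; pixel size scales by the
  factor. Fluorescence images are binned 2×2 for analysis; the fused core
  uses a total factor of 4 per axis (0.2 µm → 0.8 µm).

## Registration

Co-registration estimates a rigid shift+rotation between reference
distribution maps by exhaustive normalized cross-correlation over integer
shifts and a rotation grid (defaults ±10 px, ±10°, 0.5° steps; ties broken
toward the smallest shift, then smallest rotation; bilinear interpolation,
rotation about the image centre, counterclockwise; out-of-source pixels are
flagged invalid). Subpixel refinement is deliberately out of scope: both
modalities are first binned to the common coarse grid, where the planted
offsets of the synthetic study are integer. The pipeline does not hard-code
*which* constituent's map anchors the alignment: it tries every
(fluorescence component × Raman component) map pair and keeps the
best-correlating one — in practice the lipid-droplet maps select
themselves, since spot patterns are the most shift-discriminating.

## The synthetic study

`build_fusion_scenario` emulates the measurement layout the method was
designed for: five whole-cell fluorescence images (cells 1–5) and four
small Raman scans (two subregions on each of cells 4 and 5). Six
constituents — nucleus, nucleolus, cytoskeleton, lipid droplets, a
protein-enriched perinuclear ring, and the sample support — of which
exactly three (nucleus, cytoskeleton, droplets) are fluorescent, mimicking
DAPI/phalloidin/lipid-dye labeling; the other three have exactly zero
fluorescence emission. Raman signatures carry 3–8 positive bands each and
are deliberately blended with a common profile until all pairwise
correlations fall in 0.3–0.8, so the spectral separation problem is
realistically hard rather than orthogonal.

Study conditions (generator defaults, chosen once):

* canvas 96 × 96 native pixels at 0.2 µm (a whole cell at desk scale; the
  geometry, axes, and 2×2/4×4 binning chain are as in the measurement
  layout above);
* 57 fluorescence channels (415–695 nm, 5 nm) and 556 Raman channels
  (640–1750 cm⁻¹, 2 cm⁻¹);
* Raman subregions 32 × 32 native pixels, placed so the windows actually
  scanned contain droplets (anchoring registration) and so the nucleolus is
  absent from both cell-4 windows but present in the cell-5 windows — the
  substrate of the correspondence-of-species constraint;
* planted rigid offsets between the nominal aim point and the actual scan:
  integer shifts, multiples of 4 native pixels within ±8, i.e. integer on
  the fused 0.8 µm grid, rotation-free (rotation recovery is validated
  separately on spot phantoms);
* additive Gaussian noise, σ = 2 % of the maximum clean intensity per cube
  (a Poisson option exists for fluorescence counting realism); baseline and
  cosmic spikes are off by default and enabled where the preprocessing
  chain itself is under test.

The generator draws everything from one seed and returns the hidden truth
(maps, spectra, planted transforms, actual windows) alongside the cubes;
the fitting pipeline consumes only the cubes and the nominal aim points.

What passing recovery tests does and does not show: the generator is the
fitted model's own forward form, so at zero noise the factorization target
is exactly realizable — recovery failures would indicate algorithmic
defects, not model misfit. Real measurements add what the phantom omits:
optical point-spread functions, wavelength-dependent detector response,
non-additive baselines, spatial noise correlation, and genuine deviations
from bilinearity. Results on phantoms bound what the algorithm can do, not
what a specific instrument will deliver.

## Numerical choices

* Normal-equation solves use Cholesky with an explicit reciprocal-condition
  guard (`rcond < 1e-12` is treated as rank deficiency, with a diagnostic
  naming collinear components).
* NNLS uses block principal pivoting with a full-exchange/backoff rule and
  grouped subsystem solves; final values are clipped at zero to remove
  representation noise.
* Structural zeros: a component is dropped from a block's solve when its
  observed signature energy is below 1e-24 of the largest component — an
  exact-zero test in double precision, not a tuning knob.
* Convergence of the fusion runs is insensitive to the initializer in the
  tested regimes because the two-stage initial estimates start close to
  the solution; the iteration cap (100) is a safety net.
* Component matching in validation maximizes total cosine similarity over
  all assignments by exhaustive permutation (exact for the ≤ 8 components
  handled here; a Hungarian solver would only matter beyond that).
* Absence detection for the correspondence constraint uses a robust
  per-area peak (mean of the 8 brightest pixels) relative to the
  component's maximum across areas, threshold 0.15: genuinely present but
  sparse structures (droplets occupy < 2 % of a window) keep a high peak,
  while the diffuse leakage that rotational ambiguity spreads into truly
  absent areas stays an order of magnitude lower. A plain quantile or mean
  fails exactly on the sparse-structure case.

## Problem sizes

The default study produces a 13 568 × 613 multiset (four whole-cell
fluorescence blocks of 2 304 pixels, four fused-core blocks of 64 pixels,
four native Raman blocks of 1 024 pixels); the full pipeline — two
per-modality MCR runs, 4 × 18 registration searches, assembly, and the
incomplete-multiset fit — completes in well under a minute on one core.
These sizes are the package's validation defaults; nothing in the
implementation assumes them, and cubes are limited only by memory
(sparse/out-of-core storage is an explicit non-goal).

## Known limitations

* Rigid registration only (shift + rotation, integer-pixel search): no
  affine/nonrigid deformation, no feature matching, no subpixel refinement.
* No rotational-ambiguity band estimation; constraints reduce ambiguity but
  the returned factorization is a point solution.
* The number of components is a user decision (`svd_scree` assists); there
  is no automatic selection.
* Proprietary instrument formats are out of scope; cubes enter as
  multi-page TIFF or CSV with a JSON sidecar.
* TIFF round-trips are single-float precision (values are rescaled to
  [0, 1] with the affine factors stored in the sidecar); CSV keeps full
  double precision.
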