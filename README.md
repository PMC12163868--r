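# mcrfuse

Multimodal, multiscale hyperspectral image fusion by MCR-ALS on incomplete
multisets.

## The problem

Hyperspectral imaging platforms differ in what they see and how finely they
see it. A confocal fluorescence microscope can scan a whole labeled cell
quickly (e.g. 57 emission channels, 415–695 nm, 0.2 µm pixels), while a
Raman microscope — far slower but chemically much richer (640–1750 cm⁻¹
after preprocessing) — is typically pointed at a few small subregions of the
same cell. Classical image fusion forces both measurements onto a common
footprint: crop everything to the jointly scanned area, bin everything to
the coarsest pixel size, and discard the rest.

`mcrfuse` implements the alternative: keep **all** recorded pixels at their
native resolution by assembling one *incomplete multiset* — a single
augmented data matrix in which whole-cell fluorescence rows face a *missing*
block of Raman channels, small-area Raman rows face a missing block of
fluorescence channels, and a co-registered, downsampled *fused core* (pixels
measured by both techniques) ties the two modalities together — and unmix it
with a missing-data-aware MCR-ALS.

## The model

Unfolding an image cube gives a matrix **D** (pixels × channels) obeying the
bilinear model

```
D = C Sᵀ + E
```

with **C** the concentration profiles (distribution maps once refolded),
**Sᵀ** the pure spectral signatures, and **E** the residuals. Classical
MCR-ALS alternates the constrained least-squares updates

```
C  = D S (Sᵀ S)⁻¹          Sᵀ = (Cᵀ C)⁻¹ Cᵀ D
```

until the lack of fit, `LOF(%) = 100 · sqrt(Σe²ᵢⱼ / Σd²ᵢⱼ)`, stabilizes
(explained variance is `100 · (1 − Σe²/Σd²)`). For an incomplete multiset
the same model holds, but each row of **C** and each column of **Sᵀ** is
solved **only over the observed entries** of its row/column of **D**:

```
c(i,:)  = d(i, obs) S_obs (S_obsᵀ S_obs)⁻¹
s(:,j)ᵀ = (C_obsᵀ C_obs)⁻¹ C_obsᵀ d(obs, j)
```

No missing value is ever imputed, and the result is one full set of
concentration maps and concatenated fluorescence+Raman signatures per
constituent. Supported constraints: non-negativity on **C** and **Sᵀ**
(true NNLS or clipping), *correspondence of species* (a component's
concentration zeroed in images where it is absent) and equality-to-zero
spectral segments (e.g. null fluorescence signal for non-fluorescent
constituents).

## What's in the package

| Area | Functions |
| --- | --- |
| Containers | `hsi_cube()`, `multiset_matrix()`, `unfold()`/`refold()`, `fit_metrics()` |
| Preprocessing | `bin_spatial()`, `remove_cosmic_spikes()`, `svd_fourier_denoise()`, `asls_baseline()`, `select_spectral_range()`, `preprocess_raman()` |
| Registration & fusion | `estimate_rigid_transform()`, `apply_rigid_transform()`, `crop_to_region()`, `fuse_rowwise()` |
| MCR core | `simplisma_initial_spectra()`, `update_C()`/`update_S()`, `nnls_multi()`, `run_mcr_als()` |
| Incomplete multisets | `assemble_incomplete_multiset()`, `update_C_missing()`/`update_S_missing()`, `run_incomplete_mcr()`, `predict_missing_blocks()` |
| Synthetic phantoms | `phantom_spec()`, `generate_phantom_maps()`, `generate_pure_spectra()`, `simulate_measurement()`, `build_fusion_scenario()` |
| Pipeline & I/O | `fuse_and_assemble()`, `fit_fusion_scenario()`, `evaluate_recovery()`, `read_cube()`/`write_cube()`, `read_multiset()`/`write_multiset()`, `cli_main()` |

A thin command-line tool (installed as `exec/mcrfuse`) exposes the pipeline
as subcommands: `simulate`, `preprocess`, `align`, `fuse`, `assemble`,
`unmix`, `report`.

## Worked example

Simulate the default labeled-cell study (five whole-cell fluorescence
images; two cells additionally carry two small Raman scans each, offset from
their nominal aim points by an unknown rigid shift), run the full pipeline,
and score the result against the hidden ground truth:

```r
library(mcrfuse)

scenario <- build_fusion_scenario(phantom_spec(seed = 1, noise_sd = 0.02))
fit <- fit_fusion_scenario(scenario)
fit$model
#> <mcr_model> 6 components, 13568 pixels x 613 channels
#>   converged after 3 iterations (relative LOF change 0.0457% below tolerance 0.1%)
#> LOF 4.921 % | explained variance 99.758 %

ev <- evaluate_recovery(fit, scenario)
round(ev$spectral_cosines, 4)
#>      nucleus    nucleolus cytoskeleton     droplets      protein      support
#>       0.9999       0.9999       0.9999       0.9999       0.9999       0.9999
round(ev$map_cosines, 4)
#>      nucleus    nucleolus cytoskeleton     droplets      protein      support
#>       0.9999       0.9998       0.9998       0.9994       0.9996       0.9999
```

The model is the single joint factorization of a 13 568 × 613 incomplete
multiset (four whole-cell fluorescence blocks on top, the fused
fluorescence+Raman core of four co-registered subregions in the middle, four
native-resolution Raman blocks at the bottom). `fit$registrations` holds the
rigid transforms recovered for each subregion from the per-modality
distribution maps; the cosine tables say that every constituent's
concatenated fluorescence+Raman signature and every recoverable
concentration map matches the generator's ground truth to within ~1 %
despite the 2 % measurement noise. Maps of non-fluorescent constituents in
fluorescence-only blocks are structurally undetermined (no observed signal);
they are flagged in `fit$model$undetermined` and excluded from the score.

The same run from a shell:

```sh
mcrfuse simulate --out scenario --seed 1
mcrfuse assemble --scenario scenario --out ms
mcrfuse unmix --ms ms --out fit --incomplete
mcrfuse report --fit fit --ms ms --out report
```

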