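# mcsmt: multi-compartment microscopic diffusion imaging

`mcsmt` estimates microscopic properties of nervous tissue from multi-shell
diffusion-weighted MRI, *unconfounded* by fibre crossings and orientation
dispersion. It is aimed at diffusion-MRI researchers and methodologists who
want orientation-invariant microstructure maps (neurite density, intrinsic
diffusivity) from ordinary two- or three-shell acquisitions, plus the fibre
orientation distribution and a dispersion summary on top.

## The method

The diffusion signal of a single microdomain with orientation ω is modelled
as a two-compartment kernel

    h_b(t) = v_int · exp(−b t² λ)
           + (1 − v_int) · exp(−b t² λ) · exp(−b (1 − t²) λ⊥ext),

with t = ⟨g, ω⟩, intra-neurite volume fraction v_int ∈ [0, 1] (a "stick"
with zero transverse diffusivity), intrinsic diffusivity
0 ≤ λ ≤ λ_free shared by both compartments, and the tortuosity closure
λ⊥ext = (1 − v_int) λ for the extra-neurite "zeppelin". The key fact — the
spherical mean technique (SMT) — is that the average of the signal over
gradient directions at fixed b does not depend on the fibre orientation
distribution, and has the closed form

    ē_b = v_int · √π erf(√(bλ)) / (2√(bλ))
        + (1 − v_int) · exp(−b λ⊥ext) · √π erf(√(b(λ−λ⊥ext))) / (2√(b(λ−λ⊥ext))).

Fitting (v_int, λ) to the per-shell spherical means (after Rician noise-bias
adjustment) therefore recovers the microstructure regardless of crossings
and dispersion. A second stage deconvolves the fibre orientation
distribution with the fitted voxel-wise kernel (spherical harmonics +
positivity/normalization projection) and summarizes it by the
orientation dispersion entropy, the KL divergence from the uniform
spherical density. A Watson-mixture simulator generates ground-truth data
for validation and protocol design. See the methods vignette
(`vignettes/multicompartment-smt.Rmd`) for the full account.

## Worked example

```r
library(mcsmt)

# a small synthetic three-shell dataset: 6x6 voxels, v_int = 0.6,
# lambda = 2 um^2/ms, 30 directions/shell at b = 1000/2000/3000 s/mm^2,
# Watson-dispersed fibres, Rician noise at SNR 30
sim <- simulate_dataset(dim = c(6, 6, 1), v_int = 0.6, lambda = 2,
                        b = c(1000, 2000, 3000), n_dir = 30, snr = 30,
                        n_b0 = 6, seed = 1)
fit <- mcsmt(sim)
summary(fit)
#> Multi-compartment SMT fit: 36 voxels (0 failed, 0 at a bound)
#> Shells: b = 1000, 2000, 3000 s/mm2; lambda_free = 3.05 um^2/ms; sigma = 0.03487
#> Parameter quartiles over the mask:
#>                     q1 median     q3
#> v_int           0.5649 0.5920 0.6303
#> lambda          1.8402 1.9955 2.2071
#> lambda_perp_ext 0.7923 0.8094 0.8186
#> lambda_mean_ext 1.1592 1.2181 1.2656
```

The estimated noise level (`sigma = 0.035`) matches the simulated 1/30, and
the parameter quartiles bracket the ground truth (v_int = 0.6, λ = 2, hence
λ⊥ext = 0.8 and λ̄ext = 1.2 by the tortuosity relations). `coef()`,
`predict()`, `fitted()`, `residuals()`, `plot()` and `simulate()` work as
for any fitted-model object; `write_maps(fit, "out/")` writes float32 NIfTI
parameter maps.

Real data go through the same object:

```r
ds  <- load_dwi("dwi.nii.gz", "dwi.bval", "dwi.bvec", "mask.nii.gz")
fit <- mcsmt(ds)                       # lambda_free = 3.05 (in vivo) by default
write_maps(fit, "out/")
fv  <- fod_volume(normalize_signal(ds), fit)   # FOD SH + entropy maps
```

or through the command line (`exec/smt`, installed with the package):

```sh
smt fit --dwi dwi.nii.gz --bval dwi.bval --bvec dwi.bvec --out out/
smt fod --dwi dwi.nii.gz --bval dwi.bval --bvec dwi.bvec --out out/
smt simulate --config experiment.json --out results/ --seed 1
```

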