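# serosrr

Simulation and reconstruction toolkit for through-slice **super-resolution
diffusion–relaxation MRI** with randomly overlapping thick slices.

## The problem

High-resolution diffusion MRI is SNR-starved: thin slices carry little
signal, and at low SNR the apparent diffusivity (D) and diffusional
variance (V) are estimated with large errors, while the repetition time is
usually fixed, so T1 is not encoded at all. If instead each shot excites a
*thick* slice (aspect ratio k sub-voxels) at a **uniformly random**
through-slice position, overlapping excitation histories give every
sub-voxel its own local repetition time. The heterogeneous TR encodes T1
*and* conditions the super-resolution inverse problem, so high-resolution
parameter maps can be recovered from thick-slice data with no scan-time
penalty.

The forward model for one sub-voxel is

    S = S0 * (1 - exp(-TR / T1)) * exp(-b * D + b^2 * V / 2)

with S0 the baseline signal (a.u.), D in μm²/ms, V in μm⁴/ms², T1 in s, b
in ms/μm²; a thick-slice shot sums this over its covered sub-voxels with
their individual TR histories. Reconstruction solves, per through-slice
column of n positions (4n unknowns),

    min_x || f(x; W, TR, b) - S ||²  +  λ || Δx ||²,    x within box bounds,

with Δ the first spatial difference of each parameter vector and λ = 0.01
by default, via bound-constrained Levenberg–Marquardt with an analytic
Jacobian.

The package provides: the three sampling schemes (random overlap, slice
shifting, direct high-resolution), the thick-slice forward model with
Rician noise at prescribed SNR, randomized piecewise-smooth line phantoms
and a procedural labelled brain phantom with inscribed block letters, the
regularized solver, and an evaluation suite (RMSE accuracy / RMV precision
across an SNR sweep, plus a three-pipeline brain demonstration). Users are
researchers in quantitative MRI methods who want to prototype or stress
sampling/reconstruction choices in simulation, or fit externally measured
thick-slice magnitude stacks given a scheme file.

## Worked example

```r
library(serosrr)

cfg   <- scheme_config(seed = 1)   # 75 mm FOV, n = 50, k = 4, m = 1000, 150 ms
sch   <- sero_scheme(cfg)
scheme_statistics(sch)
#> <scheme_stats>
#>   TR quantiles (s): min=0.15  q1=1.35  median=1.8  q3=2.25  max=18.3
#>   fraction TR < 0.3 s: 0.015   mean coverage: 80.00/position

truth <- line_phantom(line_phantom_config(seed = 2))
noisy <- predict_signal(truth, sch) |>
  add_rician_noise(sigma_from_snr(truth, snr = 3), seed = 9)

fit <- fit_column(noisy, sch, fit_config(lambda = 0.01))
rmse(truth, fit$estimates)
#> # A tibble: 4 × 2
#>   parameter  rmse
#>   <chr>     <dbl>
#> 1 S0        0.894
#> 2 D         0.379
#> 3 V         1.04
#> 4 T1        1.56
```

Reading the output: every position is covered by ~80 shots whose local TRs
range from one shot spacing (0.15 s, consecutive overlap) to many seconds,
with only ~1.5% below 300 ms thanks to the slice-averaged-TR rejection
rule — that TR spread is the T1 encoding. At SNR 3 (a deliberately harsh,
noise-dominated setting; this is a single phantom and noise draw, so
expect spread around the study averages) the regularized fit recovers D to
a few tenths of a μm²/ms and returns a usable T1 map; V is the hardest
parameter because magnitude (Rician) noise biases it upward at low SNR. `autoplot(fit,
truth = truth)` overlays the estimated and true profiles;
`run_snr_sweep()` and `plot_metrics()` reproduce the full
accuracy/precision-versus-SNR study, and `run_brain_demo()` the
letter-legibility comparison of direct sampling, thick-slice fitting
without super-resolution, and the full reconstruction.

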