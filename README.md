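# ecogpipe

Motor decoding from high-density micro-electrocorticography (µECoG) grids,
end to end and fully synthetic: `ecogpipe` simulates multichannel cortical
surface recordings with known kinematic tuning, extracts binned high-gamma
band-power features, decodes three-dimensional limb kinematics with a
position-velocity Kalman filter, and reproduces the electrode-density,
cortical-coverage and channel-contribution analyses that motivate
high-density grids in the first place.

It is aimed at BCI/neural-engineering researchers and methods developers who
want a dependency-light, deterministic sandbox for decoding pipelines:
every stage has a known ground truth, so estimators can be validated against
oracles rather than eyeballed.

## The model in brief

Neural observations are per-channel high-gamma (70–150 Hz) band powers in
100-ms bins, z-scored with training-split statistics. The decoder is a
linear-Gaussian state-space model over the state
x = (pₓ, p_y, p_z, vₓ, v_y, v_z, 1):

- dynamics  x_{t+1} = A x_t + w,  w ~ N(0, W), with the position rows of A
  fixed to the kinematic identity p_{t+1} = p_t + Δt·v_t;
- observations  z_t = H x_t + q,  q ~ N(0, Q), one feature per channel.

`ecog_kalman()` fits A, W, H, Q in closed form (least squares on paired
states and features) and returns a classed model object with `print`,
`summary`, `coef`, `predict`, `simulate`, `residuals` and `plot` methods.
Performance is the mean Pearson correlation between decoded and true
position on a held-out 30% split; task throughput uses the standard
information-transfer rate log₂(N)·max(S−F, 0)/T.

## Worked example

```r
library(ecogpipe)

layout  <- ecog_layout(8, 8, pitch_um = 1250, diameter_um = 850)
layout
#> ecog_layout: 8 x 8 grid (64 channels), pitch 1.25 mm, diameter 0.85 mm
#>   span 8.75 x 8.75 mm, density 64 channels/cm^2

tuning  <- make_tuning_maps(layout, n_sources = 6, spatial_scale_mm = 1.5, seed = 11)
kin     <- make_kinematics(90, fs_kin = 100, profile = "gait", seed = 12)
session <- synthesize_session(layout, tuning, kin, noise_model(), fs = 1000, seed = 13)
session
#> ecog_session: 64 channels x 89990 samples @ 1000 Hz (89.99 s), 0 channels masked out

features <- preprocess_session(session, run_config())
res      <- decode_session(features, kin, split_ratio = 0.7, burn_in = 10)
res
#> ecog_eval: position CC (x, y, z) = 0.888, 0.890, 0.917 (mean 0.898)
#>        speed CC (x, y, z) = 0.800, 0.705, 0.868

summary(res$fit)
#> Position-velocity Kalman decoder
#>   channels: 64   bins fitted: 629   dt: 0.1 s
#>   velocity transition |eigenvalues|: 0.962, 0.962, 0.374
#>   mean observation-noise variance: 0.6117
```

Beyond decoding, the same feature/kinematics pair feeds the spatial
analyses — `density_subsets()` + `subsample_performance()` for
pitch/coverage sweeps, `rf_importance()` + `optimal_subset()` +
`contribution_map()` for channel selection, `hg_correlation()` for
inter-electrode similarity — and `run_closed_loop()` simulates assisted
cursor control on center-out or webgrids targets, scored with
`adjudicate()` and `bit_rate()`.

A thin CLI over the same functions ships at `inst/cli/ecogpipe.R`
(`simulate | preprocess | decode | subsample | contrib | task | report`),
and the benchmark preset is described declaratively in
`inst/extdata/benchmark.json`. The methods vignette
(`vignettes/methods.Rmd`) documents the generator, the estimators, and the
numerical choices in detail.

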