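# dynoct

Dynamic-contrast analysis of spectral-domain OCT speckle.

Epithelial layers with active intracellular motion decorrelate OCT speckle
on millisecond timescales, while surrounding stroma is static. `dynoct`
turns that contrast in *dynamics* into quantitative maps and segmentations:
it computes depth-resolved intensity autocorrelation curves from M-scans,
inverts them into decorrelation-time (DT) distributions by a CONTIN-style
regularized nonnegative inverse Laplace transform, maps speckle variance
over frame stacks, and segments the dynamic layer from just two sequential
frames via the normalized complex difference — even when no structural
boundary is visible. The motivating application is the urothelium of the
bladder wall, whose specific segmentation could track urothelial cancer-cell
invasion, but nothing in the code is tissue-specific.

## The model in brief

For complex circular Gaussian speckle with field autocorrelation
`g1(tau) = exp(-tau/tau_c)`, the Siegert relation gives the intensity
autocorrelation

```
G(tau, z) = <I(z,t) I(z,t+tau)> / <I(z,t)>^2 = 1 + exp(-2 tau / tau_c).
```

`compute_afc` estimates `G` per depth with 20-segment averaging;
`mean_removed_afc` gives the autocovariance normalized to 1 at zero lag.
The decaying tail is modeled as a nonnegative mixture of exponentials on a
log-spaced DT grid, `G_m = sum_n exp(-t_m / gamma_n) x_n`, solved by
minimizing

```
|| A x - G ||^2 + alpha^2 || Omega x ||^2 ,   x >= 0,
```

with `Omega` a second-difference smoothness operator and `alpha` chosen at
the L-curve corner (`select_alpha_lcurve`). Peaks of the recovered `x` are
the speckle DTs; under the Siegert relation a layer with field decorrelation
time `tau_c` peaks at `tau_c / 2`.

For segmentation, two frames acquired 50 ms apart are compared per A-line by

```
D_i = FT(sf1_i - sf2_i) / ( |FT(sf1_i + sf2_i)| / 2 + eps ),
```

the complex difference normalized to the average signal amplitude
(`complex_difference`), thresholded and cleaned into a binary mask
(`make_mask`).

A phantom simulator (`simulate_mscan`, `simulate_frame_pair`,
`synthesize_fringes`) generates layered samples with exactly known
decorrelation structure and ground-truth masks, so the entire chain is
testable without instrument data.

## Worked example

```r
library(dynoct)

# a two-layer sample: dynamic "urothelium" (tau_c = 10 ms) over static
# "stroma", equal mean amplitudes -- no structural boundary at all
spec <- phantom_spec(
  layers = list(
    layer_spec("urothelium", c(20, 90),  tau_c = 10,  amplitude = 1),
    layer_spec("stroma",     c(90, 180), tau_c = Inf, amplitude = 1)),
  n_depth = 200, noise_sigma = 0.05, seed = 1)

# --- M-scan branch: autocorrelation -> DT distribution -------------------
mscan <- simulate_mscan(spec)                       # 200 x 80,000 at 20 kHz
afc   <- mean_removed_afc(mscan, n_segments = 20, max_lag = 50)
dist  <- invert_afc(afc_profile(afc, depth = 50))   # one urothelial depth
find_dt_peaks(dist)
#>      gamma    weight prominence
#> 1 5.336699 0.1033911  0.1033911

# --- two-frame branch: complex-difference segmentation -------------------
pair <- simulate_frame_pair(spec)                   # 50 ms apart
dimg <- complex_difference(pair$frames[,,1], pair$frames[,,2],
                           noise_region = c(1:20, 181:200))
mask <- make_mask(dimg)
dice(mask, pair$truth$dynamic_mask)
#> [1] 0.9993498
```

The recovered DT peak sits at 5.3 ms — one grid bin from the theoretical
`tau_c / 2 = 5` ms that the Siegert relation predicts for a 10 ms field
decorrelation time. The two-frame mask overlaps the true dynamic layer with
Dice 0.999 despite the layers being indistinguishable in mean intensity.

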