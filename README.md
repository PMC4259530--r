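# fbpmap

Rapid mapping of visual receptive fields (RFs) from flashed-bar responses
by tomographic reconstruction, for electrophysiology (sorted spike times,
e.g. multi-electrode array recordings of retinal ganglion cells) and for
functional imaging (ROI fluorescence traces, e.g. two-photon recordings of
synaptic terminals expressing a calcium indicator).

## The idea

A bar flashed at perpendicular offset *z* along direction *φ* drives a
linear neuron in proportion to the integral of its spatial RF *f(x, y)*
over the bar's footprint.  Responses to bars at a set of parallel offsets
form one projection; repeating at a few evenly spaced angles measures the
Radon transform of the RF,

R(z, φ) = ∬ f(x, y) δ(x cos φ + y sin φ − z) dx dy,

which is inverted exactly as in computed tomography: each projection row
is multiplied in the frequency domain by a band-limited ramp filter
(Hamming apodisation, band edge 0.6 × Nyquist by default) and the filtered
rows are back-projected with cubic-spline interpolation and summed,

f̂(x, y) = π/(2N) Σ_φ R̃(x cos φ + y sin φ, φ).

Five angles suffice to recover the centre, size, shape and orientation of
typical RF centres, so a complete map takes minutes rather than the tens
of minutes needed by spike-triggered averaging of white noise; ON and OFF
response components separate by their latency windows; and the impulse
response is recovered at the recording's own resolution (8 ms bins, 125
Hz) instead of the display refresh rate.

The package implements the full workflow — stimulus protocol generation,
PSTH assembly, sinogram construction, filtered back projection,
spatiotemporal analysis, RF quantification (centre, 2-D Gaussian fit,
SNR), a spike-triggered-average baseline for comparison, and a
linear–nonlinear Poisson simulator used as its ground-truth test bed.

## Worked example

Map a simulated OFF ganglion cell with the standard retinal protocol
(5 angles × 29 positions × 3 repeats, 80 µm bars spaced 40 µm, 100 ms dark
flashes every 500 ms — 217.5 s of stimulation):

```r
library(fbpmap)

protocol <- generate_protocol(n_angles = 5, n_positions = 29,
                              bar_width = 80, position_spacing = 40,
                              flash_duration = 0.1, duty_cycle = 0.5,
                              n_repeats = 3, contrast = -1, seed = 1)
protocol
#> Flashed-bar stimulation protocol
#>   5 angles (0, 36, 72, 108, 144 deg) x 29 positions x 3 repeats = 435 flashes
#>   bar width 80 um, spacing 40 um (reconstruction resolution)
#>   flash 0.1 s, duty cycle 0.5 s, contrast -1; total duration 217.5 s

# ground-truth model cell: Gaussian RF (sigma 180 x 120 um at 20 deg),
# centred 80 um right and 40 um below the grid centre, peak burst 150 Hz
cell   <- calibrate_gain(make_model_rf("gaussian", centre = c(80, -40)), protocol)
spikes <- simulate_spikes(cell, protocol, seed = 2)   # 1390 spikes

fit <- fbp_rf(spikes, protocol, temporal = TRUE)
summary(fit)
#> Receptive field mapped by filtered back projection
#>   5 angles x 29 positions, spikes modality
#>   OFF: centre (80, 0) um, |SNR| 19.1
#>   ON: centre (-360, 360) um, |SNR| 7.6
#>   OFF fit: centre (81.1, -46.9) um, half-widths 219.0 / 150.4 um, orientation 19 deg
#>   ON fit: centre (-445.1, 253.6) um, half-widths 535.1 / 65.5 um, orientation 51 deg
```

The OFF map recovers the cell: fitted centre (81, −47) µm against the
true (80, −40) µm, orientation 19° against 20°, with SNR 19 from four
minutes of data.  (This cell has no ON component; the ON row is the
expected noise floor, with a third of the SNR and no stable fit.)  The raw
fitted half-widths include the instrument blur of the method — finite bar
width plus the band-limited filter.  Calibrating and removing it gives the
physical extents:

```r
blur <- reconstruction_blur(protocol)     # ~58 um for this protocol
deblur_half_width(coef(fit)[1, c("half_width_major", "half_width_minor")], blur)
#> half_width_major half_width_minor
#>            211.2            138.7
```

against true half-maximum half-widths of 211.9 × 141.3 µm.  The temporal
side (`fit$temporal`, `fit$impulse`) holds the 125 Hz reconstruction
movie and the impulse response differentiated from the centre's step
response.

`plot(fit)` draws the RF with the fitted half-maximum ellipse.
Fluorescence inputs run through the same interface (`fbp_rf(traces,
protocol, roi = ...)`), using baseline-subtracted response integrals in
place of spike counts.  For batch runs, `run_pipeline("config.json")`
processes every unit in a recording and writes maps, metrics and a
reproducibility manifest; `inst/cli/fbpmap.R` wraps it for the shell.

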