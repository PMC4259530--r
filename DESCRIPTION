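Package: fbpmap
Title: Receptive-Field Mapping from Flashed Bars by Filtered Back Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rapid mapping of visual receptive fields from responses
    to flashed bars, using tomographic reconstruction.  Responses to bars
    presented at pseudo-random positions and a small number of evenly spaced
    angles are assembled into peri-stimulus time histograms, collapsed into
    Radon-transform estimates (sinograms), and inverted by filtered back
    projection with a Hamming-apodised ramp filter and cubic-spline
    interpolation.  Includes spatiotemporal reconstruction at millisecond
    binning, ON/OFF component separation, orientation tuning, receptive-field
    quantification (centre, 2-D Gaussian fit, signal-to-noise ratio), a
    spike-triggered-average baseline for comparison, and a linear-nonlinear
    Poisson simulator (spikes and calcium-indicator fluorescence) for
    validation.  Works with both multi-electrode spike recordings and
    fluorescence imaging of population activity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    signal,
    tiff,
    pracma,
    withr
Config/testthat/edition: 3
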