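Package: artsort
Title: Spike Sorting Under Electrical Stimulation Artifacts with Structured
    Gaussian Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint inference of electrical-stimulation artifacts and evoked
    spikes on multi-electrode arrays. The stimulation artifact is modelled as
    a zero-mean Gaussian process with a separable Kronecker covariance over
    time, space and stimulus amplitude, built from Matern(3/2) kernels
    modulated by gamma-density variance envelopes. Spikes are detected by
    greedy template matching pursuit against known electrical images, and
    artifact and spikes are estimated jointly by per-amplitude coordinate
    ascent, seeded across amplitudes by Gaussian-process extrapolation.
    Includes hyperparameter estimation from proxy artifacts, a simplified
    (kernel-free) estimator, activation-curve fitting with probit models,
    failure diagnostics, and a synthetic-data generator for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
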