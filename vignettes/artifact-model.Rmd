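---
title: "Separating stimulation artifacts from evoked spikes: the model behind artsort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating stimulation artifacts from evoked spikes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artsort)
```

## The problem

Electrical stimulation through a multi-electrode array evokes spikes that
arrive within a millisecond or two of the current pulse — exactly when the
recording is dominated by the stimulation artifact, a structured voltage
transient tens to thousands of microvolts large. Estimating which neurons
fired on which trials (and at what latency) therefore requires estimating
the artifact jointly with the spikes. `artsort` implements a structured
Gaussian-process model of the artifact together with a template-matching
spike detector, and alternates the two estimates per stimulus amplitude.

The observation model is additive: on trial `i` of amplitude `a_j`,

    Y = A_j + sum_n M^n b^n + eps,    eps ~ N(0, sigma^2 I),

where `A_j` is the artifact at amplitude `j` (identical across trials up to
small jitter), `M^n` holds time-shifted copies of neuron `n`'s electrical
image (EI) — its spatiotemporal spike footprint over the array, assumed
known from a separate, stimulation-free recording — and `b^n` is a binary
vector placing at most one spike per neuron per trial on the sample grid
inside a spike window (default 0.25–1.5 ms after pulse onset).

## The artifact prior

The artifact stack `A(t, e, j)` is modelled as a zero-mean GP whose
covariance factorizes over the axes:

    K = rho * K_s  (x)  K_e  (x)  K_t  +  phi^2 I,

with one axis kernel each for time, electrode (space) and stimulus
amplitude, and a jitter `phi^2` absorbing small deviations from the
factored structure. Each axis kernel is a stationary Matern(3/2)
correlation, `(1 + sqrt(3) d lam) exp(-sqrt(3) d lam)`, modulated by an
unnormalized gamma-density variance envelope `d(x) = x^alpha exp(-x beta)`:
the Matern part encodes smoothness (how far information is shared along an
axis), the envelope places variance where the artifact actually lives — a
temporal bump near 0.5 ms, spatial decay away from the stimulating
electrode (negligible beyond roughly 700 um). On the stimulus axis only
smoothness is modelled (`alpha = beta = 0`). Covariates are physical —
milliseconds, micrometres, microamperes — so fitted inverse length-scales
are portable across sampling rates.

The stimulating electrode itself behaves differently: its artifact is far
larger, persists past 2 ms, and is discontinuous at known hardware
"breakpoint" amplitudes where stimulation gain settings change. It gets an
independent two-factor (time x stimulus) kernel per breakpoint range, block
diagonal in the stimulus dimension so that no information crosses a
breakpoint. Because a stationary stimulus factor spreads variance evenly
over a range while the real stimulating-electrode artifact grows steeply
with amplitude, each fitted range kernel additionally carries a
moment-matched per-amplitude scale profile (a diagonal rescaling of the
stimulus factor to the proxy's realized per-amplitude mean square); this
keeps the posterior filter from over-shrinking at the top of a range.

All linear algebra — solves, log-determinants, posterior means, sampling —
runs in the per-factor eigenbases, so the cost is cubic in the largest
single factor dimension (time, electrodes, or amplitudes), never in their
product. Factor eigendecompositions are computed once at kernel assembly
and cached with the object.

## Initialization: proxies and hyperparameters

The marginal likelihood of the raw data is intractable (it sums over all
spike configurations), so hyperparameters are fitted by maximizing the
Gaussian likelihood of a cheap proxy artifact:

* the switching artifact — the baseline present even at the smallest
  amplitude — is removed first, as the mean over trials at the lowest
  amplitude;
* for the non-stimulating kernel, the proxy pools trial means across
  stimulating-electrode datasets after translating each onto the array
  center (grid translation in row/column space), keeping the 25% of
  electrodes closest to the center; averaging across stimulating
  electrodes cancels electrode-specific spikes;
* for the stimulating electrode, the per-amplitude trial mean (or median)
  suffices, because the artifact dwarfs any spike contribution there.

Two noise parameters are estimated directly rather than optimized:
`sigma^2` as the pooled across-trial variance at the lowest amplitude on
the farthest electrode quartile (any structure common to trials cancels),
and `phi^2` as the variance of the proxy's background window (trailing 25%
of time samples, lowest informative amplitude, farthest electrode
quartile). Since the proxy is a trial mean, its background variance is
`phi^2 + sigma^2 / n_j`; the known trial-mean noise part is subtracted.
When the proxy comes from a single stimulating-electrode dataset, the
switching-mean subtraction makes the lowest-amplitude slice identically
zero and the background falls back to the next amplitude.

The remaining hyperparameters (`rho`, per-axis `lam`, `alpha`, `beta`) are
optimized by L-BFGS-B on log scales (`alpha` box-constrained in [0, 20],
`lam` in [1e-3, 1e3] per covariate unit) from a data-driven initialization
(envelope shapes from a regression of log marginal standard deviations on
the envelope covariate) plus seeded jittered restarts; the reported fit is
the best over all starts and never worse than a supplied initialization.
`rho` is optimized jointly with the length-scales; because the envelopes
are unnormalized, `rho` and the envelope magnitude trade off, so only the
implied variance profile and the length-scales are identifiable — the
tests check exactly those.

## Inference: per-amplitude coordinate ascent

Amplitudes are processed in increasing order. At each amplitude the
algorithm alternates:

1. **Matching pursuit** per trial on the artifact-subtracted residual:
   greedily accept the (neuron, onset) template with the largest squared
   -error decrease `delta = 2 <r, m> - ||m||^2` while `delta > 0`, at most
   one spike per neuron, ties broken toward the lower neuron index and
   earlier onset. A backfitting refinement then cycles over neurons,
   re-fitting each one's onset-or-absent decision given the others until
   no move improves the fit; every move strictly decreases the squared
   residual, so it terminates, and for a single neuron it coincides with
   exhaustive search. The refinement resolves overlapping-spike
   decompositions that one-shot greedy subtraction gets wrong, which
   matters at high amplitudes where all neurons fire at nearly the same
   latency.
2. **Artifact filtering**: the artifact posterior mean given the
   spike-subtracted trial mean, which shrinks each kernel eigencomponent
   by `kappa / (kappa + sigma^2 / n_j + phi^2)`. With many trials or low
   noise the filter approaches the identity and the estimate approaches
   the plain spike-subtracted mean.

The sweep loop stops when assignments are identical between sweeps
(default cap 5 sweeps; in the default scenario ≥ 90% of amplitudes
stabilize within 3). The artifact at the next amplitude is initialized by
GP extrapolation — the noise-free posterior mean given the estimates at
all lower amplitudes — which is what keeps coordinate ascent out of poor
local optima when the artifact is large. The stimulating electrode
extrapolates only within its breakpoint range; at the first amplitude
after a breakpoint its initialization is zero and the electrode is
excluded from the matching-pursuit likelihood during the first sweep.

Two cheaper variants are provided. The *simplified* method replaces
filtering by the plain spike-subtracted mean and extrapolation by copying
the previous amplitude's artifact; it needs no hyperparameters and is the
natural choice when trials are plentiful and artifacts moderate. A *trial
budget* freezes the artifact after a configurable number of trials per
amplitude and runs a single matching-pursuit pass for the rest.

### Numerical choices

* Kernel factors are symmetrized and factor eigenvalues clipped at zero
  before caching; anything below `-1e-8` times the largest eigenvalue is
  rejected as non-PSD.
* Conditional means use pseudo-inversion in the eigenbasis (zero modes
  contribute nothing), so noise-free interpolation is exact.
* Template rows whose truncation at the end of the recording cuts away
  the spike peak are excluded by the same strength threshold (default
  30 uV) that excludes weak neurons: a truncated near-zero template would
  otherwise be "matched" by noise about half the time.
* Matching pursuit accepts on raw squared-error improvement (no per-spike
  penalty); a nonnegative penalty margin is exposed in the configuration
  for robustness experiments.
* Outputs are deterministic given data, configuration and seeds.

## The synthetic-data generator

`simulate_series()` emulates the generative model the inference assumes,
with defaults chosen as a desk-scale version of a large-array experiment:
8 x 8 electrodes at 60 um pitch (hexagonal offset), 2 ms records at
20 kHz (T = 40), J = 20 amplitudes from 0.1 to 4 uA with one breakpoint
at 2 uA, 20 trials per amplitude, 4 neurons, 6 uV observation noise.
Artifacts are sampled from the structured GP itself with hyperparameters
set to reproduce the qualitative artifact structure of stimulation
experiments (temporal variance bump near 0.5 ms; spatial decay within
~700 um; smooth growth with amplitude, linear in the sd via an amplitude
envelope; an independent, much larger stimulating-electrode artifact per
breakpoint range, calibrated to 300 uV against 40 uV on the nearest
non-stimulating electrode). In a physical experiment such spike-free
artifacts would be measured pharmacologically; sampling them from the
prior is the synthetic substitute, and it means model misspecification on
real data (e.g. non-factorizable artifact components) is only partially
represented — passing tests demonstrate correctness of the machinery and
internal consistency, not field performance.

EIs are biphasic (sharp trough, slower rebound) with per-neuron waveform
width, rebound size and timing, exponential spatial decay (100 um), and a
distance-proportional propagation delay (2 m/s), so templates are
distinguishable across cells — as real EIs are; that distinguishability is
the premise of template matching. Spiking follows a normal-CDF activation
curve per neuron (thresholds 0.8–3.2 uA, slope 0.3 uA), and latency means
and standard deviations interpolate from (1.0, 0.25) ms at low spiking
probability to (0.4, 0.03) ms near certainty, reproducing the collapse of
latency variability as activation becomes reliable. These latency
endpoints are plausible values inside the spike window rather than
published measurements.

The generator also provides the perturbations used for validation (trial
subsampling, amplitude subsampling, noise injection), the mean-of-traces
baseline estimator — whose artifact absorbs the very spikes being sought
once spiking is near-deterministic — and trial-by-trial scoring: a true
positive requires the right neuron in the right trial with latency within
0.1 ms; FDR = FP / (FP + TP), false omission rate = FN / (FN + TP).

## Validation protocol and problem sizes

The acceptance suite runs, at the default desk scale: factored-vs-dense
oracle checks on 100 random instances (total dimension <= 500, relative
tolerance 1e-8); exactness of the filter limit; greedy-vs-exhaustive
matching pursuit on 500 single-neuron residuals; hyperparameter recovery
on a (T = 20, E = 16, J = 8) grid over 10 seeds; one full
simulate-fit-detect-score cycle (criterion: trial error below 2%, and the
baseline's false omission rate at the top five amplitudes at least ten
times the full method's); and the perturbation orderings (single-trial
subsampling, 20 uV noise injection, x5 artifact magnification; kernel vs
naive extrapolation under magnification) over 5 matched seeds, compared by
the median of the per-seed paired error differences. Perturbation runs
reuse the kernel hyperparameters fitted on the unperturbed series (they
are properties of the array and protocol) but re-estimate the observation
noise on the data at hand, which is part of the method's initialization.

## Known limitations

* Observation noise is modelled as white; correlated-noise pre-whitening
  is not implemented.
* Amplifier saturation and missing data are not handled.
* EIs are inputs and are never re-estimated from the stimulation data.
* The one-spike-per-trial, discrete-onset constraint is fixed.
* Multi-electrode stimulation is supported only through a single overall
  amplitude scale (the protocol's per-electrode pattern weights stay
  fixed), which reduces it to the single-electrode machinery.
* With very few trials and a variance-misspecified kernel the filter's
  shrinkage bias can exceed its noise reduction on strong artifacts; the
  simplified estimator is the pragmatic fallback there.
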