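---
title: "Selective spike sorting: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective spike sorting: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selsort)
```

## The generative model

A single extracellular channel is modelled as the superposition of the
activity of $N$ neurons plus noise,

$$ v(t) \;=\; \sum_{n=1}^{N} (\delta_n \ast w_n)(t) \;+\; \eta(t), $$

where $\delta_n(t) \in \{0,1\}$ is neuron $n$'s impulse train, $w_n(\tau)$ its
distinct spike waveform of length $\tau \approx 2.5$ ms (60 samples at
24 kHz), and $\eta$ background noise. Spike sorting is the inverse problem:
recover $N$, the templates $w_n$ and the trains $\delta_n$ from $v$ alone.
The package's pipeline mirrors the generative chain stage by stage:
detection recovers the combined impulse sequence
$\hat\delta = \sum_n \delta_n$; clustering splits the detected waveforms into
putative neurons; regression recovers templates; a noise-whitened likelihood
assigns what clustering could not — chiefly superimposed (overlapping)
spikes.

All sample indices in the package are 1-based, and a spike time marks the
sample at which the template attains its positive peak.

## The simulator

`simulate_recording()` draws per-neuron Bernoulli impulse trains (thinned to
an absolute refractory period), convolves them with distinct biphasic
templates, and adds faint "neighbour neuron" spikes plus white Gaussian
noise whose SD is a stated fraction of the unit spike peak. The defaults
reproduce the structure of the public simulated benchmark this class of
sorters is usually evaluated on: three neurons, 60 s at 24 kHz, about 1100
spikes per neuron per minute (per-sample rate $7.8\times10^{-4}$), noise
levels quoted relative to spike amplitude, and near-coincident cross-neuron
spikes arising naturally at these rates (roughly a fifth of all spikes have
a companion within one template length). Templates are sums of Gaussians
with physiological widths: a 0.1–0.25 ms depolarisation peak followed by a
wider, 0.25–0.6 ms repolarisation trough and an optional small
pre-depolarisation dip; candidates correlated above 0.95 with an existing
template are redrawn.

What the simulator deliberately does not emulate: electrode drift, bursting
(amplitude adaptation within a train), biphasic-negative spike polarity,
multi-channel geometry, and non-Gaussian system noise. Tests passing on this
generator therefore certify the algorithmic chain under the model's own
assumptions, not performance on any particular tissue preparation.

The exact signal/neighbour/noise decomposition of a rendered trace is kept
in the recording's `components` attribute, so conservation (`trace ==
signal + neighbour + noise`) is testable bit for bit, and the benchmark
MAT-file dialect (`read_benchmark()` / `write_dataset()`) round-trips the
trace, spike times and class labels.

## Detection: cepstrum of the bispectrum

The channel is treated as a sparse, positively skewed impulse sequence
driving an unknown spike-shaped filter in Gaussian noise. Because all third
cumulants of a Gaussian process vanish, the bispectrum
$B_v(n,m) = \mathrm{E}[V(n)V(m)V^*(n{+}m)]$ of the trace exposes the filter
alone:

$$ \log|B_v(n,m)| = \mathrm{const} + L(n) + L(m) + L(n{+}m),
   \qquad L = \log|F|. $$

Averaging a row of $\log|B|$ over $m$ leaves $L(n)$ plus a constant (the
cyclic sums are independent of $n$), so the filter's log-magnitude spectrum
drops out directly; its overall scale — which carries the skewness of the
driving sequence — is irrelevant to peak positions. A minimum-phase transfer
function is rebuilt by cepstral folding, inverted with a Tikhonov floor
($\epsilon = 10^{-3}$ of the spectral maximum), and applied to the trace.
Numerical choices that matter:

* **Bispectrum estimation**: Hann-tapered segments of 1024 samples, 50%
  overlap, at most 128 segments averaged (evenly subsampled beyond that).
* **Dynamic-range clamp**: the recovered log spectrum is clamped to 6 nats
  below its maximum. Near-null spectral bins — exact zeros on noise-free
  input — otherwise produce a ringing inverse filter that smears each
  impulse response across the whole segment.
* **Detection statistic**: the absolute value of the inverse-filtered,
  stationary-wavelet-denoised trace. The minimum-phase reconstruction
  cannot capture the true filter's all-pass component, so each spike leaves
  a short oscillatory, sign-indefinite response; magnitude thresholding
  (median + 4 MAD-SDs) is robust to that.
* **Localisation**: each detection claims the raw-trace maximum within
  ±20 samples, strongest response first; a detection whose claimed peak
  falls within 16 samples (`min_event_gap`) of an existing claim is the same
  spike and is dropped. An amplitude gate at 4 robust SDs of the trace
  removes faint multi-unit activity from distant neurons, which the
  amplitude-blind inverse filter would otherwise report; because the gate is
  relative, detection stays invariant to amplitude scaling and DC offset.

Denoising uses an exact frequency-domain à-trous stationary wavelet
transform with the standard coiflet-3 filter bank, soft-thresholding all
detail bands at the universal threshold estimated from the finest band.

Overlapping spikes more than `min_event_gap` apart yield separate events;
closer collisions coalesce into one event and are deferred to the matcher.

## Features and clustering

Aligned waveforms (61 samples spanning one full template, peak at index 20,
4× spline interpolation for sub-sample alignment) are decomposed by a full
orthonormal Haar transform; rows are zero-padded to a power of two, which
keeps the transform exactly norm-preserving. For every coefficient the
Kolmogorov–Smirnov distance between its standardised empirical distribution
and the standard normal CDF (Lilliefors-style: mean and SD estimated from
the data; the statistic itself, no p-value) ranks deviation from normality,
and the ten highest-ranked coefficients form the feature set. Multimodal
coefficients — those that separate neurons — deviate most. Each selected
feature's kernel density (`feature_pdf()`) reports its number of
substantive modes so the visual cross-check is also automatable.

Two extraction defaults deviate from the settings used for the raw
61-electrode recordings this method was first applied to (31-sample windows,
peak at the 12th sample, which `extract_waveforms()` keeps as its own
defaults): `sort_channel()` uses the full 61-sample template span, because
the 31-sample window cuts off the repolarisation trough that discriminates
strongly correlated templates, and interpolation factor 4, because ±1-sample
alignment jitter otherwise splits a class into satellite clusters in feature
space.

Clustering is super-paramagnetic: waveforms are q-state Potts spins
(q = 20) on a mutual K-nearest-neighbour graph (K = 11), with interaction
strength $J_{ij} = \frac{1}{\hat K}\exp(-e_{ij}^2/2a^2)$ decaying with
feature distance. Swendsen–Wang cluster updates (500 recorded sweeps plus
20% burn-in, compiled code, explicit seed) estimate the spin–spin
correlation $G_{ij}$ on a temperature grid 0–0.25 in steps of 0.01; at
$T = 0$ the exact limit is returned analytically. Clusters are connected
components of edges with $G_{ij} > 0.5$; components below 60 members join
the unassigned pool. These defaults follow the conventions of the
established SPC-based sorting tools; none of them is sharp, and all are
exposed in `spc_config()`.

**Choosing the working temperature.** The cluster count along the grid
traces the phases: magnetised (correlated classes still fused),
super-paramagnetic (classes apart), shattered. Two observations fixed the
rule. First, genuine spike classes persist over many grid steps, while
accidental agglomerations — typically a cluster of overlap waveforms, the
starred group familiar from SPC sorting tables — melt after a single step;
counts observed at fewer than two adjacent temperatures are therefore
ineligible. Second, within the eligible set the count is maximised (that is
the super-paramagnetic phase), ties broken towards the most waveforms
assigned, which lands on the phase's coolest point before spins start
leaking into the unassigned pool. A single compact class thus resolves at
the lowest grid temperature. OPTICS (`optics_cluster()`) is provided as the
feature-free alternative, operating on raw aligned waveforms with
DBSCAN-style extraction at a cut radius; non-core border points stay
unassigned.

## Templates, noise model, whitening

Each cluster's impulse train regressed against the voltage gives the
putative template by Toeplitz least squares: the train's autocorrelation
matrix against the train–voltage cross-correlation at lags −L..L (L = 40,
so a peak-marked spike's full support is covered). With isolated spikes
this is exactly the spike-triggered average; with overlaps the off-diagonal
terms deconvolve the interference. Singular systems fall back to a
pseudo-inverse with a warning.

Subtracting every clustered spike leaves a residual whose biased
autocovariance (61 lags) defines the noise model. The whitening filter is
the centre column of the inverse matrix square root $C^{-1/2}$ of the
autocovariance's Toeplitz matrix — symmetric, unit-norm, an impulse for
white noise, and wavelet-like in shape for structured noise. The square
root matters: the pipeline filters the voltage *and* re-estimates templates
on the filtered trace, so the subsequent matched-filter product computes
the optimal statistic $w^\top C^{-1} v$; using the inverse itself would
apply $C^{-1}$ twice and measurably lowers the matched SNR on correlated
noise.

## Prediction and elimination

For every event the clustering left unassigned, each neuron is scored with

$$ L_n = \frac{w_n^\top v_{\mathrm{win}} - \tfrac12\lVert w_n\rVert^2}
             {\sigma^2} + \log\frac{p_n}{1-p_n}, $$

the Gaussian matched-filter log likelihood with a Bernoulli prior from the
neuron's estimated firing rate $p_n$; $\sigma^2$ is the robust noise
variance of the whitened trace. Because a near-synchronous overlap pulls
the best single-template fit to a position *between* the two true spikes —
where greedy subtraction then wrecks the second spike — the matcher scores,
alongside every single-neuron explanation, every two-neuron joint
explanation (including the template cross-correlation term at the candidate
lag difference) and keeps whichever model wins: nothing, one spike, or an
eliminated pair. Accepted templates are subtracted from the working trace
before later targets are scored. The lag scan spans ±30 samples because a
coalesced overlap event can hold its secondary spike up to half a template
away from the detected peak. Acceptance requires $L > 0$ (posterior favours
presence); a neuron with an existing spike within the refractory period of
a candidate time is neglected at that lag; scoring is confined to detected
event indices, never to arbitrary trace maxima.

## Evaluation

Sorting results are scored by one-to-one spike matching within ±1 ms
(±24 samples; the matcher is provably maximum-cardinality for this interval
structure and is cross-checked in the tests against an independent
augmenting-path matching), with cluster-to-neuron correspondence chosen by
an exact assignment over the confusion matrix (all permutations up to eight
clusters, greedy beyond). Overlap events are true spikes with a companion
from another neuron within one template length; they are reported as total
/ detected / correctly sorted. Reconstruction places each neuron's template
at its accepted spike times, and the squared Pearson correlation between
the summed reconstruction and the recording gives the coefficient of
determination (in percent). Note its ceiling is set by the noise floor: at
noise level 0.05 the signal fraction of variance caps it near 90%, however
good the sorting.

## Problem sizes and determinism

The bundled tests exercise the full chain on 10-second channels and the
acceptance checks on the benchmark-shaped 60-second, 24 kHz configuration
at noise levels 0.05–0.15, plus 200 constructed two-template collisions
(lags 3–30 samples, noise 0.1) for overlap resolution; `scripts/acceptance.R`
re-runs the same computations from a command-line seed. Every stochastic
component — simulator, Monte-Carlo sweeps — takes an explicit seed, and
fixed seeds reproduce recordings, cluster assignments and metrics bit for
bit.

## Known limitations

* The minimum-phase assumption in the inverse filter localises but does not
  fully re-compress spikes whose true transfer function has a significant
  all-pass part; localisation leans on the raw-peak claim step.
* A single global inverse filter blends all templates; channels whose units
  differ greatly in spectral shape will see per-unit localisation biases
  (absorbed by the ±20-sample claim window).
* Elimination depth is two templates per event; triple near-coincidences
  are not resolved.
* The amplitude gate intentionally discards sub-threshold multi-unit
  activity; lowering `amp_gate_k` trades false positives for sensitivity to
  faint units.
* OPTICS on raw waveforms is O(M²) in time; it is the alternative, not the
  default, for long recordings.
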