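---
title: "Reconstructing extracellular spikes from downsampled low-pass recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing extracellular spikes from downsampled low-pass recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Extracellular electrophysiology carries two kinds of information at very
different rates. Local field potentials (LFPs) live below roughly 200 Hz
and can be captured at low sampling rates; single-unit action potentials
("spikes") are millisecond-scale biphasic transients whose energy sits
above the LFP band and conventionally requires sampling at tens of kHz.
Recording only the low band at a low rate reduces data volume and
power — attractive for chronic and wireless recording systems — but
apparently discards the spikes.

The premise of this package is that a realisable low-pass filter does
not discard them completely. A fourth-order Butterworth filter rolls off
smoothly, so a residue of above-cutoff energy leaks into the retained
band, and the spike's own low-frequency content (its net area) produces
a small, stereotyped deflection in the LFP-band trace. A learned
sequence-to-sequence model can exploit both cues to re-synthesise the
spike-band signal at full temporal resolution. `spikesr` implements that
pipeline end to end: preprocessing, the 1D shifted-window attention
network, spike-focused training, reconstruction, and the spike-level and
network-level evaluation suite — plus a synthetic-recording generator so
that every stage is testable without any experimental data.

## Signal model and preprocessing

A wideband trace sampled at `fs` (25 kHz by convention here) is split
with *zero-phase* fourth-order Butterworth filters at a 200 Hz cutoff
into a low-pass input band and a high-pass ground-truth band. Zero-phase
means the filter is applied forward and backward (`butter_split()`), so
each band has the squared magnitude response and no phase delay; because
Butterworth low- and high-pass responses are power-complementary, the
two bands sum back to the input, which the test suite asserts to 1e-6
away from the trace edges. An ideal brick-wall split (`mode = "ideal"`)
is provided as an ablation switch: it zeroes Fourier coefficients
outside the band, removing the above-cutoff residue entirely.

The low band is then subsampled by an integer factor `M` (1, 8, 16 or 25
are the studied grid) *without* further anti-aliasing — the pipeline
order is deliberately filter-then-subsample — and re-upsampled by
`L = M` with Fourier-method interpolation (`fourier_resample()`:
zero-padding the DFT, splitting the Nyquist coefficient for even
lengths). The interpolant passes exactly through the retained samples,
so input and ground truth share one time base with no phase shift.

Each electrode's (interpolated input, high-pass ground truth) pair is
normalised by a single scale: the maximum absolute value of the
high-pass trace over its *background-noise* samples. Background is
defined deterministically as everything farther than 2 ms from any
crossing of −5σ, where σ is the robust noise SD `median(|x|)/0.6745`.
The estimator and the mask are design choices: the robust σ is the
field-standard spike-resistant estimator, and the crossing-based mask
makes the scale independent of spike amplitude. Normalisation is per
electrode; rescaling by `scale` restores microvolts exactly.

## The reconstruction network

The model (`swin1d_config()`, `build_spk_model()`) is a 1D adaptation of
the residual shifted-window transformer used for image restoration.
Every time sample is one token: a shallow 1D convolution (kernel 3)
lifts the length-`T` window to `C` channels (the shallow feature); a
stack of residual blocks — each a sequence of window-attention
transformer layers plus a convolution and a residual add — produces the
deep feature; the two are summed (global skip) and a final convolution
projects back to a single channel. Because the input is pre-interpolated
to the target resolution, there is no upsampling layer anywhere: output
length equals input length by construction, and the test suite asserts
this for every configuration it builds.

Attention details are the package's own choices where the 2D reference
architecture had to be specialised to 1D: non-overlapping windows of 8
tokens, a cyclic shift of 4 tokens on every second layer with masked
attention at the wrap-around seam, 6 heads by default, pre-norm
LayerNorm, GELU MLP with expansion 2, and a learned relative-position
bias table of size `2 * attn_window - 1` per head. The reference
configuration is `T = 128`, `C = 180`, 6 blocks of 6 layers, kernel 3.

Three comparison families (`build_baseline()`) are provided at
matched parameter budgets: the same attention trunk fed the
*downsampled* window and finished with a 1D sub-pixel-shuffle upsampler;
a residual CNN (262 channels, 16 blocks) with the same upsampler; and a
causal dilated temporal CNN (554 channels, 6 blocks) that consumes a
127-sample pre-interpolated window and emits one sample. Their parameter
counts are checked against independent per-layer enumeration in the
tests.

The forward and backward passes are written directly in vectorised
base R (a chunk of windows is a single `(G*T) x C` matrix; attention is
evaluated per window-block through precomputed index maps), and every
gradient is checked against central finite differences in the test
suite. Training (`train_network()`, or the `spike_sr()` front end)
minimises mean squared error with Adam at a fixed learning rate; the
reference schedule — 200 epochs, batch 16, learning rate 1e-4 — is the
package default.

## Spike-focused window selection

Spikes are sparse: at a few Hz, almost all uniformly drawn 5.12 ms
training windows are spike-free, and a model trained on them happily
converges to predicting silence. Spike-focused window selection (SFWS)
biases the batch: the first half of every batch is anchored on a
ground-truth spike peak, jittered by an integer `tau` drawn uniformly
from `(-W/2, W/2]`, so the peak lands uniformly at any position of the
window; the second half remains uniform random. The anchored half is a
guarantee — the suite asserts that all `B/2` anchored windows contain
their peak in 1000 consecutive batches and that the anchored peak
position is uniform by a chi-square test over 1e5 draws. A uniformly
drawn second-half window can still contain a spike by chance, so "a
batch contains exactly B/2 spike windows" holds only up to that
binomial-rate collision, which the test accounts for explicitly.

Ground-truth peaks are indexed by the same detector used for
evaluation: excursions below −6σ, with crossings closer than 1 ms
merged into one event (a design choice sized to spike width at
25 kHz), timestamped at the most negative sample.

## Reconstruction and evaluation

A full trace is reconstructed by sliding the length-128 window at a hop
of 64 samples and merging overlapping predictions by a centre-weighted
(raised-cosine, floored) sample-wise average
(`reconstruct_sequence()`). The merge rule is a design choice where
the procedure was unstated. A plain mean was the first candidate, but
per-window diagnostics show reconstruction quality is uniform across
the window *except* within a few samples of its edges, where the
attention context is one-sided and spike amplitude drops by almost
half; a uniform mean dilutes exactly the spikes that straddle a
neighbouring window's edge. Centre-weighting discounts edge
predictions, and because the weights are renormalised by their
accumulated sum the merge remains exact for identical overlapping
predictions: the identity sanity check (a stub network returning its
input reproduces the trace at any stride) still holds to machine
precision. The final window is right-aligned to the trace end so every
sample is covered without phantom padding.

Evaluation mirrors standard spike metrics. Detection at −6σ of the
ground-truth background noise; reconstructed timestamps within ±500 µs
of a ground-truth timestamp count as correctly restored. Matching is
one-to-one and *optimal*: a dynamic programme over the two sorted trains
maximises the number of matches and, among maximisers, minimises the
total absolute delay. A greedy nearest-first pairing was considered and
rejected because it is provably sub-optimal on crossing configurations
(gt = [0, 6], rec = [4, 10] at tolerance 5 loses one match), whereas the
test suite requires exact agreement with brute-force enumeration on
1000 random instances. Hit rate is TP/(TP+FN), precision TP/(TP+FP).
Waveform fidelity is the RMS error between ground-truth and
reconstructed traces over −1 to +2 ms around each matched ground-truth
timestamp, normalised by that window's peak-to-peak amplitude (NRMSE);
averages are over correctly restored spikes, aligned on ground-truth
timestamps.

Downstream analyses: 50 ms-bin rate histograms; Pearson correlation
matrices between electrode pairs' histograms (undefined pairs from
constant histograms are flagged `NA`); PCA of spike waveforms (centred,
unscaled — amplitude is informative) with K-means on the first two PCs,
k = 2 or 3, scored by best-permutation agreement; and a Hamming-window
STFT (1250-sample window, 1125 overlap at 3125 Hz). A 1250-sample
window is sometimes paired with a stated "616 FFT points", which
cannot both hold literally; the package defaults to transform length =
window length and offers `n_freq = 616` as a compatibility convention
(transform length `2*(n_freq-1)`, frame truncated), without claiming
either as canonical.

K-means uses Hartigan–Wong with 10 restarts under a fixed seed rather
than a k-means++ initialisation (not available in base R); the restarts
serve the same robustness purpose and the result is deterministic under
the seed.

## The synthetic-recording generator

`simulate_recording()` emulates what the pipeline consumes: 25 kHz
multichannel traces that superpose (i) biphasic spike templates — a
sharp negative Gaussian lobe (FWHM = width, 1 ms default, −100 µV
default peak) followed by a broader positive rebound at half amplitude,
on a ~4 ms support with tapered zero tails; (ii) sinusoidal LFP
components (50 µV at 2 Hz, 30 µV at 8 Hz, 10 µV at 30 Hz by default,
random phases) standing in for slow network rhythms; and (iii) white
Gaussian background noise (10 µV SD default, optionally 1/f-shaped).
Units fire as Poisson processes (5 Hz default) in which an event
expands, with probability 0.2, into a burst of 3 spikes at 4–10 ms
intervals — tonic firing plus burst behaviour — under a 2 ms absolute
refractory period. Spikes whose template support would cross a trace
edge are dropped, not truncated. `simulate_population()` adds pairwise
co-firing: a channel pair with probability `p` shares a common Poisson
process of rate `p` times the firing rate, the second copy jittered
within ±1 ms by default.

The defaults were chosen once as representative of spontaneous
dissociated-culture activity on a planar array (spike-to-noise ratio 10,
firing a few Hz, LFP tens of µV) and are the conditions under which the
acceptance checks run. What the generator does *not* emulate —
electrode drift, spatially correlated noise, waveform variability
within a unit, true seizure dynamics, measured MEA noise spectra —
bounds what passing tests show: they validate the pipeline's mechanics
and learnability under controlled conditions, not performance on any
particular experimental preparation.

## Numerical and scaling choices

*Zero-phase realisation.* Forward–backward filtering uses odd
(anti-symmetric) edge extension with a pad of about `12 fs / cutoff`
samples, long enough for the order-4 transient at a 200 Hz cutoff to
decay below 1e-9; complementarity and gain identities are asserted away
from the edges.

*Weight initialisation.* Truncated normal (sd 0.02) for attention and
MLP weights and the bias table, fan-in uniform for convolutions,
LayerNorm at (1, 0); all reproducible under a seed, and seeded training
is bitwise reproducible on one thread.

*Problem sizes in the checked study.* The full-scale reference model
(11.8 M parameters, hundreds of electrode-hours of training data, GPU
time scales) is out of desk-scale reach, so the package's end-to-end
verification study is scaled down:
an 8-channel, 2-minute synthetic recording at factor `M = 8`; a tiny
network (`T = 128`, `C = 16`, 2 blocks of 2 layers, 4 heads, ~10.8 k
parameters) trained for 2000 Adam steps on six electrodes;
reconstruction of a 30 s segment of each of the two held-out
electrodes at stride 64. The scaled run uses learning rate 5e-3 with
`beta2 = 0.99` and gradient-norm clipping at 1: at the full-scale
defaults (1e-4, 0.999) the tiny model is still in its silent-output
phase after thousands of steps, whereas the faster schedule reaches
spike-reconstructing solutions inside the budget, and the clipping
suppresses the occasional unstable batch step that a short high-rate
run is prone to. These are training-run choices for the small model,
documented here; the package defaults remain the reference settings
(1e-4, 0.999, no clipping, 200 epochs). Under the
scaled conditions the trained model recovers the majority of held-out
spikes at −6σ/±500 µs while the interpolated input alone recovers
essentially none (its rare "hits" are chance coincidences of LFP
troughs), and disabling SFWS at identical budget and seed does not do
better — the expected direction of the spike-focused-selection
ablation.

## Known limitations

- Training cost is the dominant limit: the pure-R engine is exact but
  roughly two orders of magnitude slower than a GPU framework, so the
  full-scale configuration is buildable and testable (parameter counts,
  forward shapes) but not trainable here.
- The optimal matching is `O(n m)` in the two train lengths per
  electrode; fine for minutes of data, not for hours at high rates.
- The generator's spike templates are deterministic per unit; spike
  sorting on synthetic data is therefore easier than on real
  recordings.
- Checkpoints store double-precision weights; there is no
  cross-framework checkpoint import.
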