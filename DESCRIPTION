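Package: spikesr
Title: Reconstruction of High-Frequency Extracellular Spikes from
    Downsampled Low-Pass-Filtered Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recovering millisecond-scale extracellular action
    potentials from heavily subsampled, low-pass-filtered multichannel
    voltage recordings. Implements the full pipeline: zero-phase
    Butterworth band splitting, integer subsampling, Fourier-method
    re-interpolation and noise-referenced pair normalisation; a 1D
    shifted-window multi-head self-attention transformer trained with
    spike-focused window selection; sliding-window full-trace
    reconstruction; spike detection, train matching and waveform-error
    metrics; and downstream spike-train analyses (rate histograms,
    Pearson correlation matrices, PCA + K-means spike sorting, STFT
    spectrograms). A synthetic-recording generator with known ground
    truth makes every stage testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
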