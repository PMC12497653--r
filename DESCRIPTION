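Package: holomap
Title: High-Throughput Optogenetic Connectivity Mapping by Model-Based Compressed Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for inferring monosynaptic connectivity from two-photon
    holographic ensemble stimulation experiments. Provides a biophysically
    detailed simulator of voltage-clamp circuit mapping experiments (trial-wise
    and continuous 20-kHz modes), a 1D convolutional U-Net for demixing and
    denoising optogenetically evoked postsynaptic currents recorded at high
    stimulation rates, a coordinate-ascent variational inference engine with
    isotonic plausibility regularization (CAVIaR) that jointly estimates
    synaptic weights, presynaptic spikes, optogenetic power curves, observation
    noise and spontaneous currents, a post hoc false-negative rescue step,
    canonical waveform recovery, map-comparison metrics, leave-one-hologram-out
    cross-validation, and compressed-sensing baselines (CoSaMP and a
    spike-and-slab variational ablation) for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
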