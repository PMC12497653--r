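---
title: "Model-based compressed sensing for holographic connectivity mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based compressed sensing for holographic connectivity mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Mapping monosynaptic connectivity onto a patched postsynaptic neuron with
two-photon optogenetics is slow when candidate presynaptic neurons are
stimulated one at a time: each of N candidates needs repeated stimulation at
several laser powers, and the experimenter must wait for every evoked
postsynaptic current (PSC) to decay before the next stimulus. `holomap`
implements the computational side of a much faster protocol: holographic
stimulation of R-neuron ensembles at rates of 30--50 Hz, a learned
demixing network that isolates the PSC attributable to each stimulus even
when trials overlap in time, and a model-based compressed-sensing algorithm
(CAVIaR: coordinate-ascent variational inference with isotonic
regularization) that reconstructs the synaptic weight vector from the
demixed responses.

Everything here runs on simulated data produced by the package's own
experiment simulator, which is a first-class, tested component: it defines
the study conditions under which all quantitative claims in the test suite
are evaluated.

# The simulated experiment

A circuit of N candidates is drawn by `sample_ground_truth()`:

* A fraction `connect_rate` (default 0.1) of neurons is connected; of those,
  20% are *strong*, with synaptic charge transfer (the weight, in pA ms)
  uniform on [500, 1500], and 80% are *weak*, with a shifted-exponential
  distribution (shift 50, mean 200 pA ms). Unconnected weights are exactly
  zero. With double-exponential PSC kinetics these charges correspond to
  peak amplitudes of roughly 40--115 pA (strong) and 4--35 pA (weak); the
  weak tail deliberately extends well below the amplitudes typically
  reported for detected connections in slice experiments, so that recall is
  measured against connections at and below the detection limit.
* Optogenetically evoked spiking is a linear-nonlinear-Bernoulli model:
  neuron n spikes on trial k with probability
  `plogis(phi0_n * I_nk - phi1_n)`, where `I_nk` is the laser power (mW).
  The per-neuron coefficients are uniform, `phi0 ~ U(0.10, 0.20)` and
  `phi1 ~ U(3, 6)`, chosen so that well-expressing cells spike with
  probability near 1 at the maximal power (60 mW) while poorly expressing
  cells remain unreliable at 30 mW — the regime that makes per-neuron power
  curves necessary.
* Spike latency follows a right-shifted gamma distribution whose mean obeys
  an inverse-square dependence on power
  (`latency_min + latency_alpha / (latency_beta * I^2)`, defaults 3 ms +
  3600/I^2), so onsets at 30--60 mW fall 4--7 ms after the stimulus —
  inside the 3--12 ms admissible initiation window used throughout.
* Each transmitted PSC is a unit-integral double-exponential kernel
  (`tau_r ~ U(0.5, 2)` ms, `tau_d = tau_r + U(6, 12)` ms for the inhibitory
  preset) scaled by the weight and by log-normal trial-to-trial amplitude
  noise with median 1 (`sigma_mult = 0.2`).
* Trial-wise mode corrupts each independent 45-ms window (900 samples at
  20 kHz, stimulus at sample 100) with a Gaussian-process draw
  (RBF kernel, variance 25 pA^2, lengthscale 1 ms) plus i.i.d. noise
  (variance 4 pA^2); continuous mode builds one long 20-kHz recording by
  convolving spike trains with the kernels, adds a Poisson train of
  spontaneous PSCs (`spont_rate` Hz; charges from the weak-weight family)
  and AR(1) noise (coefficient 0.95, innovation s.d. 1 pA), then cuts
  overlapping 900-sample windows. At 50 Hz consecutive windows share 500
  samples, which is precisely the confound the demixer must remove.

Stimulus designs (`design_stimulus()`) randomly partition all N targets
into R-neuron holograms each sweep (the last hologram takes any remainder,
so every target is stimulated exactly once per sweep), randomize hologram
order and per-trial power over the discrete power set {30, 45, 60} mW, and
can reuse a fixed set of partitions when repeated holograms are needed
(leave-one-hologram-out designs). Any fixed neuron is included in a trial
with probability R/N, so revisits take N/(R f) seconds on average
(`expected_revisit_interval()`).

# Neural waveform demixing

`nwd_build()` constructs a sequential 1D U-Net: four contraction blocks
(2x temporal decimation, 1D convolution, batch normalization, ReLU) and
four expansion blocks (a stride-1 transposed convolution, batch
normalization, ReLU, 2x linear interpolation), with skip connections at
matching temporal resolutions and a final linear convolution. A stride-1
transposed convolution is algebraically a convolution with a flipped
kernel, so for learned kernels the expansion blocks are implemented as
convolutions and all upsampling is carried by the interpolation step.
Inputs of 900 samples are right-padded to 912 (so four 2x decimations are
exact: 456/228/114/57) and cropped on output. The default network
(channels 8/16/16/16, kernel width 9) has ~17k parameters; convolutions
run in C as accumulating BLAS products.

Training data (`make_training_set()`) follow the generative recipe of the
demixing task: each example sums independent *previous-trial*, *target*,
and *next-trial* PSC components with Poisson counts (defaults 2.2 / 1 / 2,
matched to the confound load of 50-Hz ensemble stimulation), onsets
outside / inside / after the admissible initiation window, random kinetics
from the selected preset, and log-normal charges spanning the simulated
weight range; plus a GP noise draw and i.i.d. noise whose variance is
itself uniform-random. The regression target is exactly the target
component; a configurable fraction (10%) of examples are pure noise with
all-zero targets, teaching the network to silence PSC-free windows. Each
trace (input and target alike) is normalized by its peak absolute
amplitude; the factor is inverted on output, so demixing is
scale-equivariant.

Two departures from a full-scale training run are deliberate, and both are
config fields:

* **Optimizer.** At full scale the network would be trained by plain SGD
  for thousands of epochs. The package targets two to three orders of
  magnitude fewer gradient steps, where SGD leaves the output amplitude
  visibly biased; Adam (lr 0.002) reaches a usable optimum within ~1000
  steps and is the default, with three warm-restart segments (optimizer
  moments reset, weights kept) that reliably pull runs out of the poor
  early optima single-schedule Adam occasionally settles in at these step
  counts. `optimizer = "sgd"` restores the classic recipe.
* **Charge calibration.** Any MSE-trained denoiser is a shrinkage
  estimator: under residual uncertainty its output is the conditional
  mean, which under-estimates PSC amplitude, and the monotone-decay
  correction removes a little more charge. At reduced training scale this
  bias is material (the demixed-to-true charge ratio is ~0.55--0.65).
  `nwd_calibrate()` measures the multiplicative bias on fresh held-out
  synthetic examples and stores its inverse in the model; `demix()`
  applies it to every output. The calibration is estimated once, from
  synthetic data only.

`demix()` finishes with the monotone-decay correction: after sample
`t_monotone` (default: end of the initiation window plus three mean rise
time constants, ~21 ms) the output is recursively clamped to
`N_t = min(N_t, N_{t-1})`. The correction is idempotent and never
increases a sample.

# The CAVIaR engine

The statistical model ties the demixed charge of trial k,
`y_k = integral of the demixed trace`, to the circuit:

* `y_k ~ Normal(w' s_k, sigma^2)`, `sigma^-2 ~ Gamma(t_sh, t_ra)`;
* `w_n ~ Normal(u, b^2)` (weight prior; `b^2` defaults to a robust scale
  of the observations);
* `s_nk ~ Bernoulli(plogis(phi0_n I_nk - phi1_n))` with a bivariate normal
  prior on `(phi0, phi1)` truncated to the positive quadrant.

Inference is coordinate ascent on a fully factorized variational
approximation. One outer iteration performs, in order: the conjugate
Gaussian block update of the weight posterior `(mu, Omega)`; the conjugate
gamma update of the noise precision (residual moments evaluated
analytically from `E[w w'] = Omega + mu mu'` and the Bernoulli moments);
per-neuron spike updates in a freshly randomized neuron order, each
immediately followed by the isotonic plausibility check; Laplace updates
of each power-curve coefficient posterior (damped Newton with a log
barrier enforcing positivity, sharpened three times, with backtracking
line search; the posterior covariance is the inverse Hessian at the mode);
and the spontaneous-current update.

Design choices that the model class leaves open, and what this
implementation does:

* **Conservative power-curve prior.** The prior mean `(0.05, 4)` puts the
  spike probability at the maximal power at ~0.27 — *below* the
  plausibility threshold. A neuron is therefore only retained when the
  likelihood actively lifts its inferred spike rate; neurons whose spike
  posteriors merely follow the prior are disconnected. This is what makes
  the plausibility rule selective, and it is the main line of defense
  against false positives.
* **Warm-up.** The disconnect rule and the spontaneous-current update are
  held for the first five outer iterations. Both read residuals of the
  fitted model; during the first sweeps the spike posteriors are still
  diffuse, the residuals are dominated by that diffuseness, and engaging
  either rule early measurably eliminates true connections.
* **Power-curve averaging.** The per-power mean spike rate averages over
  *all* trials where the neuron was targeted, with masked trials entering
  at their enforced zero: a masked window contains no detectable PSC and
  is therefore evidence of a non-spike. Averaging only over unmasked
  trials would estimate P(spike | PSC present), which is close to 1 for
  every neuron and destroys the rule's selectivity.
* **Masking statistic.** The trial mask uses a noise-floor-regularized
  lag-1 sample autocorrelation: the ordinary autocorrelation of a demixed
  PSC is near 1, but a trained demixer emits *smooth* near-zero residue on
  PSC-free windows, whose autocorrelation is also high; dividing by
  `sum(x^2) + T * floor^2` shrinks the statistic toward zero exactly for
  traces at the noise floor. The defaults (threshold 0.5, floor 4 pA) were
  calibrated once so that at least 95% of pure-noise windows are masked
  under the default noise configuration. The floor sets the method's
  detection limit: demixed PSCs below roughly 130 pA ms are treated as
  non-events, which deliberately trades recall of the weakest connections
  for precision.
* **Spontaneous currents and the adaptive threshold.** Positive residuals
  are soft-thresholded, with the penalty shrunk geometrically until the
  residual norm is at most 5% of the observation norm; trials whose total
  inferred spike probability exceeds `theta_orthog` carry no spontaneous
  current. `theta_orthog = 1` ("no confident spike on this trial") rather
  than a bound near zero: with diffuse spike posteriors for unresolved
  weak candidates, a near-zero bound never opens the gate and disables the
  estimator. The detection rate `lambda_spont = mean(z > 0)` is added to
  the plausibility threshold, so every unexplained-event process — real
  spontaneous PSCs and residual demixing error alike — raises the bar a
  putative connection must clear.
* **Stopping.** The outer loop stops when the weight posterior mean moves
  by less than `1e-5` of its largest entry, or after `max_iter` (50)
  iterations. Because the spike updates are Monte-Carlo (M = 100 draws
  from the truncated marginals), the posterior mean jitters at a level
  above the tolerance and fits typically run to the iteration cap; the cap
  is the effective compute budget.

## Post hoc processing

`false_negative_scan()` revisits disconnected neurons greedily by the
number of detected spontaneous events coinciding with their stimulation;
if assigning those events as spikes satisfies the isotonic criterion at
maximal power, the neuron is reconnected with posterior summaries from the
sample statistics of the coincident events. `estimate_waveforms()` solves
the non-negative ridge problem `min_{R>=0} |C - Lambda' R|_F^2 +
gamma |R|_F^2` by projected gradient from the projected ridge solution
(tolerance 1e-8), using the inferred spike matrix rather than the raw
design matrix so that trials without photoactivation do not bias the
canonical waveforms. `compare_maps()` reports the coefficient of
determination over full weight vectors plus precision/recall of binarized
connectivity (nonzero weight = connected, matching the fit's hard
disconnect rule). `loho_cv()` refits the model with each hologram held
out and predicts the held-out mean response per power by averaging
posterior predictive samples (weights from the Gaussian posterior,
power-curve coefficients from their truncated marginals, spikes from the
resulting Bernoulli probabilities; 500 samples per cell).

## Baselines

`cosamp()` is the standard compressive sampling matching pursuit on the
binary stimulated/not-stimulated matrix, given the true number of
connections; because it has no model of stochastic, power-dependent
spiking, its weight estimates average over trials with presynaptic
failures and are biased toward zero. `cavi_sns()` runs the same
variational engine with the isotonic rule, masking and spontaneous
estimation disabled and a simple posterior spike-rate threshold — an
ablation in the style of earlier spike-and-slab mapping methods, not a
line-by-line reimplementation of any of them.

# Problem sizes used by the tests

The packaged test-suite reproductions run at desk scale, chosen as the
package's own benchmark configuration: a shared demixing network (two
candidates trained on 2,500 examples for 30 epochs each; the one with the
smaller calibrated charge error on held-out examples is kept); robustness
runs with N = 300 candidates,
20-target ensembles at 50 Hz for 30 s of stimulation (1,500 trials, i.e.
100 stimuli per neuron) at 1 Hz and 20 Hz spontaneous rates over five
seeds; baseline comparisons on the same runs plus a single-target 10-Hz
control. `scripts/acceptance.R` re-runs the same pipeline end to end and
writes the headline numbers as JSON.

# Known limitations

* The simulator emulates voltage-clamp recordings with stationary noise,
  single-spike responses, and no short-term plasticity, photocurrent
  artifacts, access-resistance drift, or polysynaptic recruitment. Passing
  tests demonstrate internal consistency of the method under the stated
  generative model, not performance on real recordings.
* At the reduced training scale the demixer leaves ~100--200 pA ms of
  residual charge noise per window. Together with the masking floor this
  sets a detection limit: connections below ~150 pA ms (peak amplitudes
  below roughly 10 pA) are frequently missed, so recall is materially
  below what a fully trained network achieves, while precision and the
  accuracy of detected weights are preserved.
* Coordinate ascent with the sticky disconnect rule has local optima. In
  small-data regimes (fewer than ~20 stimuli per neuron) the randomized
  update order occasionally settles in a basin that drops a true
  connection and misallocates its charge to co-stimulated neurons; the
  false-negative scan recovers only the cases that left a spontaneous
  trace. More stimuli per neuron, in our experience, is the reliable cure.
* The Monte-Carlo spike update keeps the estimator the algorithm is
  specified with even though the logit expectation has a closed form
  under the logistic sigmoid; the sampling noise is part of the method's
  observed behavior (e.g. fits running to the iteration cap).
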