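---
title: "Diffusion-based synthesis of biomedical signals: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-based synthesis of biomedical signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the
probabilistic model, the network, the simulator that stands in for real
recordings, the evaluation metrics, and the places where the design was
genuinely open and a choice had to be made.

## The diffusion model

A signal set is an array of `n` signals with `C` channels and `L`
timesteps. The forward process corrupts each signal with Gaussian noise
over `T` steps under a variance schedule $\beta_t$; composing the steps
gives the closed-form marginal
$x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\varepsilon$
with $\bar\alpha_t = \prod_{s\le t}(1-\beta_s)$. The reverse process is
a learned Gaussian chain whose mean is derived from a noise-prediction
network $\varepsilon_\theta$ and whose diagonal variance is the
log-linear interpolation
$\log\Sigma_\theta = v_\theta \log\beta_t + (1-v_\theta)\log\tilde\beta_t$
between the posterior variance $\tilde\beta_t$ and $\beta_t$, with
$v_\theta \in [0,1]$ a second network output.

**Schedules.** `make_schedule()` offers two shapes. The *linear*
schedule spaces $\beta_t$ evenly from $10^{-4}$ to $0.02$; those
endpoints are calibrated for $T \approx 1000$, where
$\bar\alpha_T < 10^{-4}$ and the terminal state is effectively standard
normal. At the short schedules used for desk-scale work ($T = 100$) the
same endpoints leave $\bar\alpha_T \approx 0.37$, i.e. the chain never
reaches its stationary distribution, and samples drawn from $N(0, I)$
start from the wrong law. The *cosine* schedule (squared-cosine
$\bar\alpha$ curve, offset $0.008$, $\beta$ clipped at $0.999$) drives
$\bar\alpha_T$ essentially to zero at any $T$; all scaled-down training
runs in this package therefore use `schedule_kind = "cosine"` with
`T_steps = 100`, while `linear` with $T = 1000$ remains the appropriate
default at full scale.

**Loss.** Training minimizes
$L_{\text{simple}} + \lambda\,L_{\text{vlb}}$ with $\lambda = 10^{-3}$:
the mean-squared noise-prediction error over uniformly sampled
timesteps, plus the per-step KL term of the evidence lower bound
(Gaussian log-likelihood at $t = 1$). The reverse mean is treated as a
constant inside the vlb term (stop-gradient), so that term trains only
the variance head — learning the variance requires *some* vlb signal,
but letting it drive the mean is a well-known source of instability at
small $\lambda^{-1}$-scale batch sizes.

**$t = 1$ convention.** $\tilde\beta_1 = 0$ exactly (it is kept that
way in the schedule table, and the final sampling step adds no noise).
The learned-variance interpolation and the $t=1$ decoder likelihood
need a finite $\log\tilde\beta$, so they use the clipped value
$\log\tilde\beta_2$ — the standard practice for learned-variance
models. Timesteps are $1..T$ in the mathematics and in every user-facing
argument; storage vectors are indexed the same way, so no off-by-one
mapping exists in the code.

**Normalization.** Signals are mapped per channel to $[-1, 1]$ by an
affine transform fitted on the training set and inverted on all model
output. Without it the Gaussian terminal state and these $\beta$ ranges
would be mismatched to the data scale (CBF amplitudes are ~6 units).

**Sampling.** Ancestral sampling iterates the reverse kernel from
$t = T$ to 1. Two stabilizations are exposed: `clip_denoised` clamps
the implied clean-signal estimate to the normalized range before
forming the posterior mean (identical to the raw mean whenever the
estimate is already in range), and `var_mode` selects the reverse
variance — the learned interpolation (default), or the analytic bounds
$\tilde\beta_t$ / $\beta_t$. On short schedules the $\tilde\beta$
lower bound gives marginally cleaner samples and is what the
acceptance-scale experiments use.

**Early stopping.** A seeded 90/10 split is held out; the validation
ELBO is evaluated each epoch on a *fixed* set of timesteps and noise
draws, which removes estimator variance from the early-stopping signal.
Training stops after `patience` epochs without improvement and returns
the best-validation weights.

## The network

The noise model is a symmetric 1D U-Net. Each level applies residual
blocks (group norm, SiLU, width-3 convolutions, additive timestep
embedding per block), optional single-head self-attention over the time
axis, and a strided-convolution downsample; the decoder mirrors this
with nearest-neighbour upsampling and concatenates the matching encoder
feature map before its blocks. The head emits $\varepsilon_\theta$ and
$v_\theta$ (sigmoid-bounded). Design points that were open:

* *Downsampling* is a strided convolution rather than max pooling —
  pooling discards phase information that the decoder cannot recover;
  the symmetric strided/nearest pair behaves better in practice at
  these depths. (`maxpool` remains in the toolbox for the classifier.)
* *Attention* is standard single-head dot-product attention, enabled by
  default only at the coarsest level, where the sequence is short and
  the quadratic cost is negligible.
* *Group normalization* (groups of at most 8 channels) keeps
  small-batch training stable where batch norm would not.
* *Depth*: three levels for 64–144-step signals; the signal length must
  be divisible by $2^{levels-1}$.
* *Conditioning*: a class label becomes a learned embedding added to
  the timestep embedding (initialized with standard deviation 0.5, so
  the classes are separable to the blocks from the first epochs — a
  near-zero initialization leaves desk-scale runs class-agnostic for
  too long). A conditioning signal is concatenated channel-wise with
  the sampling state and refined by the stem convolution at every
  reverse step. An earlier variant fused the concatenation back down
  to the input channel count with a width-1 convolution first
  ([inject_signal_condition()] still exposes that primitive); for
  single-channel signals that is a scalar blend of state and condition
  — an information bottleneck under which restoration demonstrably
  fails — so the network consumes the concatenated channels directly.

Everything — forward, backward, Adam — is implemented in R with BLAS
matrix products (convolutions via im2col). The test suite checks the
analytic gradients of every parameter group against numerical
differentiation, which is the load-bearing correctness argument for a
hand-written backward pass.

## The simulator

`generate_simulated()` produces the classical cylinder–bell–funnel
family: class 0 a plateau (cylinder), class 1 a linear ramp with an
abrupt drop (bell), class 2 a jump with a linear decay (funnel), plus
two composites (bell-then-funnel, two cylinders) to reach five classes.
Within-class variation follows the classical construction: event
amplitude $\sim N(6, 1)$, additive white noise of unit standard
deviation, and Gaussian jitter of the event boundaries
(`pattern_var`, in squared timesteps — variance 100 at the default
512-step length, scaled to 4 for 64-step desk runs so the relative
jitter is comparable). Degradation models mirror the noise types a
biosignal pipeline meets: white (thermal) noise; low-frequency
sinusoidal baseline wander standing in for electrode-contact drift
(1–3 sinusoids, periods at least a quarter of the record); sparse
motion-artifact spikes (Poisson count, width 1–3 samples); contiguous
masked gaps with an explicit observation mask; and decimation followed
by linear re-interpolation to the native length, so conditional inputs
always match the model's dimensions.

What the simulator does *not* emulate: physiological morphology (QRS
complexes, activity-specific accelerometry), heteroscedastic or
correlated sensor noise, and inter-subject variability. Passing the
recovery tests here shows the machinery learns and restores
distributions of this complexity class — it does not certify clinical
fidelity on real recordings.

## Metrics

*Wavelet coherence.* The analytic Morlet CWT ($\omega_0 = 6$, dyadic
scales, $dj = 0.25$) of both signals; coherence is the squared modulus
of the smoothed cross-spectrum over the product of smoothed power
spectra, clipped to $[0,1]$. Smoothing (scale-dependent Gaussian in
time, 3-point boxcar across scales) is mandatory — unsmoothed
single-realization coherence is identically 1. The set-level score
averages the map over time, scale, and channels for seeded random
real/synthetic pairs (capped at 1000; per-signal transforms are cached
so each CWT is computed once) and reports 100 times the mean, matching
the 0–100 convention. Identity self-pairing scores exactly 100.
Constant signals have undefined phase; their coherence is defined as 0
with a warning.

*Discriminative score.* Real signals are labelled 1, synthetic 0; a
2-layer LSTM (hidden 64, forget-gate bias 1, full BPTT, Adam, early
stopping on a held-out slice) is trained on a stratified 80/20 split
and $|{\rm accuracy} - 0.5|$ on the test fold is reported. The
"classification error" phrasing in the literature is reconciled with
near-zero-is-good tables by exactly this $|a - 0.5|$ convention, which
is what the score's originators compute.

*UMAP overlay.* Both sets are flattened and embedded **jointly** (one
shared embedding — separate embeddings would not be comparable), via
the `umap-learn` reference implementation invoked through `python`;
coordinates are deterministic for a fixed `random_state`. No R
implementation of UMAP is available in this stack, and re-deriving the
algorithm would add nothing to the package's contribution.

*F1.* One-vs-rest TP/FP/FN per class with the $0/0 \to 0$ convention
and macro averages; validated in the tests against a brute-force
confusion-matrix oracle on random labelings.

## Scaled-down study sizes

The property and recovery experiments run at sizes a single CPU
handles comfortably, chosen once: 64-timestep CBF signals; $n = 256$
training signals for unconditional recovery (held-out 32 for scoring);
3 classes × 100 for label conditioning (up to 40 epochs — class
faithfulness converges more slowly than marginal fidelity); $T = 100$
cosine schedule; a 3-level U-Net with 16 base channels (~163k
parameters); at most 30 epochs with early stopping (patience 10) for
the unconditional run. Signal-conditional models train 25 epochs
(thermal denoising, whose MSE target is tight) or 15 (gap imputation,
whose zero-fill baseline is loose) — the conditioning input carries
most of the information and convergence is much faster than in the
unconditional case. Restoration point estimates average a few
conditional draws (posterior-mean estimation); a single draw samples
the posterior and carries its full spread. The discriminative score uses sets of 64; coherence
scores use 200–256 pairs. The class-imbalance experiment subsamples
one class to 5%, trains the pinned 1D-CNN (16/32-channel conv-pool
blocks, dense softmax head) on the imbalanced and rebalanced sets, and
compares macro-F1 on an untouched test set over three seeds.

One identifiability point drives the data choice for restoration. The
classical CBF construction carries intrinsic white noise of unit
standard deviation; that noise is part of the "clean" reference but is
statistically unrecoverable from a further-degraded copy. With added
thermal noise of sd 0.3, even a *perfect* posterior sampler has
expected restoration MSE $2\sigma_e^2\sigma_n^2/(\sigma_e^2+\sigma_n^2)
\approx 0.165$, worse than the 0.09 MSE of simply keeping the noisy
input — denoising in that regime is ill-posed. Real restoration
targets (ECG morphology) have structured, low-broadband-noise
references; the restoration experiments therefore use CBF signals with
intrinsic noise sd 0.1, so the added corruption dominates what is to
be removed.

## Known limitations

* Quality at $T = 100$ and 30 epochs is deliberately modest; the
  coherence of generated sets approaches the real-versus-real ceiling
  at this noise level (~60/100 for 64-step CBF) but clinical-grade
  synthesis would need longer schedules, larger networks, and GPUs.
* The R implementation is single-threaded BLAS-bound; it is sized for
  hundreds, not hundreds of thousands, of signals.
* Degradations are applied afresh each epoch when training
  signal-conditional models (the model learns the degradation family,
  not fixed pairs); restoration is therefore *blind* within that
  family — the model is never told the realized noise level.
* Checkpoints are RDS archives; NPZ import/export covers `values` +
  `labels` arrays only (WFDB and other device formats are out of
  scope).
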