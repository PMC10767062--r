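---
title: "Stimulus reconstruction and group inference for cortical tracking of music"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus reconstruction and group inference for cortical tracking of music}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musetrack)
library(dplyr)
```

## The problem

Low-frequency cortical activity phase-locks to the amplitude envelope of a
continuous auditory stimulus ("cortical tracking" or "neural tracking"). A
standard way to quantify this coupling from EEG is *stimulus reconstruction*:
a backward temporal response function (TRF) that maps the multichannel neural
response at a window of time lags back onto the stimulus envelope. The
Pearson correlation *r* between the reconstructed and the original envelope
of a held-out epoch is the *reconstruction accuracy*, and behavioral
predictors of that accuracy — here *familiarity* with a musical excerpt,
trait *mind wandering*, and *repetition* — are tested with linear mixed
models with crossed Subject and Stimulus random intercepts.

`musetrack` implements that pipeline end to end, together with a synthetic
study generator with a known forward model, so that every stage can be
verified by parameter recovery without access to any particular EEG data set.

## The decoder

The backward model reconstructs the envelope sample at time $t$ as

$$\hat s(t) = \sum_n \sum_\tau d(t + \tau, n)\, g(\tau, n),$$

where $d(t, n)$ is the response of channel $n$, $\tau$ ranges over integer
sample shifts, and $g$ minimises the penalised squared error, giving the
closed form $g = (D^\top D + \lambda I)^{-1} D^\top s$ with $D$ the lagged
design matrix and $\lambda$ a ridge penalty. `ridge_fit()` solves the normal
equations by Cholesky factorisation rather than an explicit inverse; at
$\lambda = 0$ on a rank-deficient design it falls back to the minimum-norm
solution with a warning.

**Lag window.** The default window runs from 200 ms before to 350 ms after
the stimulus sample. At the 64 Hz analysis rate the bounds fall between
integer samples ($-12.8$ and $22.4$); `lag_grid()` floors both bounds, giving
shifts $-13 \dots 22$ — 36 shifts including zero. Flooring both bounds is
the package's canonical rounding convention; round-to-even or symmetric
rounding would give 35 or 37 shifts.

**Cross-validation.** `nested_loo_decode()` holds out each epoch in turn
(outer leave-one-out); a second LOO nested in the training set scores each
candidate $\lambda$ (default grid $10^{-6} \dots 10^{6}$ by decades) by mean
inner-fold Pearson r. Ties are broken toward the larger $\lambda$ (more
regularisation). The winning $\lambda$ is refit on all training epochs
jointly — lagged matrices stacked with no cross-epoch lags — and applied to
the held-out epoch, so 32 epochs per participant yield 32 models and 32
accuracies per participant. Channels and envelopes are z-scored per epoch
before fitting; Pearson scores are invariant to this, but it keeps a single
$\lambda$ scale meaningful across epochs. Per-epoch Gram matrices are
precomputed once, making each inner fold a cheap matrix downdate.

## Envelope extraction

`cochlear_envelope()` follows peripheral-auditory practice: a bank of
band-pass filters with centres equally spaced on the ERB-rate scale
$\mathrm{ERBrate}(f) = 21.4 \log_{10}(1 + 0.00437 f)$, each band about one
equivalent rectangular bandwidth wide (realised as 4th-order Butterworth
band-passes applied forward-backward), subband envelopes as analytic-signal
magnitudes, and their arithmetic mean as the single envelope. The bank's
size and range are configurable; the defaults (38 filters, 30 Hz–7.5 kHz)
follow common cochleagram practice since no single canonical setting exists.
The envelope is then band-passed 1–9 Hz with a zero-phase 4th-order
Butterworth filter and resampled to 64 Hz (`bandlimit_resample()`), mirroring
the EEG preprocessing contract; the band-pass itself provides anti-aliasing
because the retained content lies far below the output Nyquist frequency.

**Epoching.** A 60-s trial minus a 500-ms onset discard does not divide
evenly into two 30-s epochs. `epoch_trace()` therefore emits consecutive
full epochs and keeps a trailing fragment of at least half an epoch, so a
trial becomes one 30-s and one 29.5-s epoch and sixteen trials give 32
epochs. EEG and envelope are epoched with identical boundaries, keeping the
pair sample-aligned.

## Behavioral indicators

`code_familiarity()` codes High when the answer to *"Do you know this
music?"* at the **first** presentation is *Yes*, Low for *No* or *Not sure*;
the code propagates to second-presentation epochs, so second-presentation
answers can never change a code. `code_mind_wandering()` maps the four
percentage bins to midpoints (12.5, 37.5, 62.5, 87.5), averages within
subject, and codes a subject High when their mean exceeds the grand mean of
subject means. Two conventions are deliberate: the grand mean is a mean of
subject means (not of pooled trials), and a subject exactly at the grand
mean is coded Low — a deterministic, conservative tie rule. Missing
first-presentation answers are hard errors; nothing is imputed.

## Group inference

`null_distribution()` builds chance-level accuracies by mismatched pairing:
each reconstruction is correlated with envelopes of other epochs under
random derangements that never pair an epoch with its own stimulus content
(the other presentation of the same excerpt carries the same envelope and is
also excluded). `compare_to_null()` is a paired t-test of per-subject
observed minus null means, with Cohen's d = mean/sd of the differences.

`fit_lmm()` fits the crossed random-intercepts model by REML through
lme4/lmerTest and reports Wald-t p-values with Satterthwaite degrees of
freedom, 95% Wald CIs, standardized coefficients (refit on the z-scored
response with binary predictors coded ±0.5), and variance-partition
marginal/conditional R². `stepwise_backward()` reduces the full
three-indicator factorial in two phases — random intercepts by REML
likelihood-ratio tests at α_random = 0.1 (a model with no random effects is
compared on the same REML criterion, including the fixed-design log
determinant), then fixed terms by Satterthwaite F at α_fixed = 0.05,
dropping the largest non-significant p first while respecting marginality.
Random-effect LRT p-values are not halved for the boundary problem, matching
the plain-LRT convention of the elimination-table layout this mirrors.
Likelihood-ratio comparisons of fixed effects always refit by ML.
`follow_up_by_level()` refits the inner familiarity model within each
mind-wandering level.

```{r example, eval = FALSE}
cfg <- sim_config(n_subjects = 8, n_channels = 8, seed = 1)
run <- run_pipeline(cfg, lambda_grid = 10^seq(-2, 4, 2))
run$null_comparison
tidy(run$best_model)
```

## The synthetic generator

The generator inverts the decoding problem with an explicit forward model:

* **Envelopes** are 1–9 Hz band-limited Gaussian noise, offset and rectified
  to be nonnegative (a cochlear envelope cannot go below zero), then
  low-passed at 9 Hz to remove rectification harmonics.
* **EEG** channels are causal convolutions of the envelope with per-channel
  damped-oscillation kernels (random frequency 2–8 Hz, decay 50–150 ms,
  random amplitude topography, support 0–350 ms), plus 1/f-shaped noise
  band-limited to 1–9 Hz and scaled so the channel-wise RMS amplitude ratio
  equals the trial's SNR. With zero noise the decoding problem is exactly
  identifiable, which is what makes noise-free recovery a sharp test.
* **Design**: 8 stimuli (first half designed familiar) × 2 presentations ×
  60 s per subject, cut into 30-s epochs; 21 channels at 64 Hz.
  First-presentation answers match the designed label with probability 0.80
  (familiar) and 0.67 (unfamiliar) — the agreement rates the emulated study
  reported; misses split 2:1 between *No* and *Not sure*. Each subject has
  a latent mind-wandering propensity (logit-normal around 0.25 for the
  designed-low and 0.65 for the designed-high group); per-trial bins are the
  propensity plus trial noise cut at 25/50/75%.
* **SNR structure**: cell SNR from `snr_map` times multiplicative log-normal
  subject and stimulus effects — the generative counterpart of the crossed
  random intercepts fitted downstream. The default map (0.25/0.25 low-MW,
  0.35/0.22 high-MW for familiar/unfamiliar) encodes a familiarity advantage
  only under high mind wandering, the qualitative pattern the inference
  stage is designed to detect; the absolute values are calibration choices,
  not empirical claims.

Note one deliberate asymmetry: SNR follows the *designed* stimulus label,
while the downstream indicator is coded from each subject's *answers*.
With imperfect answer agreement the answer-coded familiarity effect is an
attenuated version of the planted designed-label contrast — the same
measurement situation a real study faces when excerpts are categorised by
individual responses.

What the generator does *not* emulate: eye blinks and other artifacts,
electrode-specific noise topographies, audio waveforms (envelopes are drawn
directly), and any nonstationarity across a session. Passing recovery tests
therefore demonstrates the correctness of the estimation machinery under the
stated model, not robustness to real-world artifacts — artifact cleaning is
delegated to upstream tooling.

`simulate_accuracy_records()` is a second, lighter generator on the
*accuracy* scale: it draws per-epoch accuracies directly from the crossed
random-intercept model with planted familiarity effects per mind-wandering
group. Power and type-I studies of the model-selection and follow-up stages
use it, because re-running EEG decoding hundreds of times would only add
Monte-Carlo noise around the same question.

## Numerical choices and problem sizes

* Ridge systems are solved by Cholesky; the brute-force cross-check
  (gradient-based minimisation of the penalised objective) agrees to
  better than 1e-6 relative error on random instances.
* Filtering uses `signal::filtfilt` (zero phase); the analytic signal is
  computed by the FFT construction.
* Verification runs use scaled-down study sizes chosen once: noise-free
  recovery decodes one participant's 32 epochs with 6 channels; SNR
  monotonicity uses 20 fifteen-second epochs per level with 8 channels;
  selection-consistency and dissociation studies use 30 subjects with
  subject/stimulus/residual SDs 0.035/0.03/0.08 on the accuracy scale and a
  planted familiarity effect of 0.06 (≈ 0.7 residual SD). With these
  conditions random-intercept retention and familiarity power are both near
  1; what limits exact model recovery is backward elimination's own
  retention of null terms at α_fixed = 0.05. Because the last surviving
  candidate is effectively the minimum-p term among the null candidates, a
  pure-null run retains *some* spurious fixed term roughly
  $1 - 0.95^{7} \approx 30\%$ of the time (measured: ~33% family-wise, with
  per-main-effect rates near 20%), and about one planted-effect run in four
  keeps a spurious term alongside the real one. `lmerTest::step` returns
  identical selections on the same data, so this is a property of the
  procedure, not of this implementation — worth keeping in mind when reading
  any backward-reduced table.

## Limitations

* Real-EEG ingestion is adapter-based: anything that can be shaped into a
  channels × time matrix with a sampling rate can enter at
  `epoch_trace()`/`nested_loo_decode()`; format parsing, re-referencing, ICA
  and channel interpolation are out of scope.
* The decoder is the plain multivariate backward TRF with ridge
  regularisation — no forward (encoding) models, no banded or boosting
  regularisation, no source-space analysis.
* Mind wandering is dichotomised at the participant level by design; no
  continuous per-trial covariate model is provided.
* The null distribution is one convention (mismatched pairing) among
  several; it is labelled as such in the outputs.
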