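# musetrack

Stimulus reconstruction and mixed-model group inference for studies of
**cortical tracking of music** with EEG — plus a fully specified synthetic
study generator, so the entire analysis chain can be validated by parameter
recovery.

`musetrack` is aimed at auditory-neuroscience researchers who relate the
reconstruction accuracy of a continuous stimulus envelope to behavioral
indicators such as stimulus familiarity, self-reported mind wandering, and
repetition.

## What it computes

**Backward TRF decoder.** The amplitude envelope $s(t)$ of the stimulus is
reconstructed from the multichannel EEG $d(t, n)$ through a lag-indexed
linear filter $g(\tau, n)$:

$$\hat s(t) = \sum_{n}\sum_{\tau} d(t + \tau, n)\, g(\tau, n),
\qquad g = (D^\top D + \lambda I)^{-1} D^\top s,$$

where $D$ is the lagged design matrix and $\lambda$ a ridge penalty. The
default window (−200 ms to +350 ms at 64 Hz) spans 36 sample shifts
including zero. `nested_loo_decode()` selects $\lambda$ by a leave-one-out
loop nested inside each outer training fold and scores each held-out epoch
with the Pearson correlation $r$ between $\hat s$ and $s$.

**Envelope features.** `cochlear_envelope()` computes an ERB-spaced
filter-bank (cochleagram) envelope; `bandlimit_resample()` applies the
1–9 Hz zero-phase Butterworth band-pass and 64 Hz resampling;
`epoch_trace()` cuts both modalities into aligned 30-s epochs.

**Behavioral indicators.** `code_indicators()` codes Familiarity (High =
first-presentation "Yes"), Mind Wandering (subject mean of bin midpoints vs
grand mean), and Repetition.

**Group inference.** `null_distribution()`/`compare_to_null()` test observed
accuracy against a mismatched-pairing null (paired t, Cohen's d);
`fit_lmm()` fits `Reconstruction ~ … + (1|Subject) + (1|Stimulus)` with
Satterthwaite tests, standardized betas and marginal/conditional R²;
`stepwise_backward()` reduces the full factorial model; and
`follow_up_by_level()` refits the familiarity model within each
mind-wandering level.

**Synthetic studies.** `sim_config()`/`simulate_study()` generate envelopes,
forward-modelled EEG (causal kernels + 1/f noise at controlled SNR) and
questionnaire answers with known ground truth;
`simulate_accuracy_records()` generates accuracy-scale records from the
crossed random-intercepts model for power/type-I studies.

## Worked example

```r
library(musetrack)

cfg <- sim_config(n_subjects = 6, n_channels = 8,
                  trial_duration = 30, epoch_duration = 15,
                  p_answer_familiar_given_familiar = 1,
                  p_answer_unfamiliar_given_unfamiliar = 1, seed = 7)
run <- run_pipeline(cfg, lambda_grid = 10^seq(-2, 4, 2), n_permutations = 30)
run
#> musetrack pipeline run  [config 49a53ed1 seed 7 ]
#>   6 subjects, 192 epochs
#> Null comparison:
#>   observed_mean_r null_mean_r t_statistic   dof    p_value cohens_d n_subjects
#> 1           0.702     0.00180        18.6     5 0.00000837     7.57          6
#> Reduced model: Reconstruction ~ Familiarity + MindWandering +
#>     Familiarity:MindWandering + (1 | Subject) + (1 | Stimulus)
```

Matched decoding (mean r = 0.70) is far above the mismatched-pairing null
(≈ 0.002): the decoder tracks the stimuli. The default generator plants a
familiarity advantage only under high mind wandering, and the follow-up
models recover exactly that dissociation:

```r
subset(run$follow_up$summary, term == "FamiliarityHigh",
       c(level, estimate, conf_low, conf_high, p_value))
#>   level      estimate    conf_low  conf_high    p_value
#> 1   Low -0.0007406953 -0.09795638 0.09647499 0.98573017
#> 2  High  0.1022586161  0.01294207 0.19157516 0.03110355

glance(run$best_model)[, c("r2_marginal", "r2_conditional")]
#>   r2_marginal r2_conditional
#> 1       0.107          0.882
```

The familiarity effect is absent in the low mind-wandering group
(β ≈ 0.00, p = 0.99) and present in the high group (β = 0.10, p = 0.031);
most explained variance comes from the Subject and Stimulus intercepts
(conditional ≫ marginal R²), as is typical for this kind of data.

`plot_accuracy_by_condition(run$records)` draws the cell means ± SEM,
`plot_reconstruction()` overlays a reconstructed envelope on the original,
and `autoplot()` on a fitted model gives a coefficient forest plot.

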