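#' Synthetic study configuration
#'
#' Parameters of the synthetic listening study used to verify every pipeline
#' stage by parameter recovery. Defaults mirror the emulated design: 8 piano
#' excerpts presented twice (16 sixty-second trials) cut into 30-s epochs, 21
#' EEG channels at a 64 Hz analysis rate, and first-presentation familiarity
#' answers matching the designed labels at rates 0.80 (familiar) and 0.67
#' (unfamiliar).
#'
#' `snr_map` gives the linear-amplitude signal-to-noise ratio of the cortical
#' tracking signal per (designed familiarity, mind-wandering group) cell; its
#' default plants a familiarity advantage only in the high mind-wandering
#' group, the qualitative pattern the analysis stage is designed to detect.
#' Per-subject and per-stimulus multiplicative log-normal effects spread SNR
#' around the cell values, matching the crossed random-intercept structure of
#' the downstream mixed model.
#'
#' @param n_subjects Number of participants.
#' @param n_stimuli Number of stimuli (default 8; the first half is designed
#'   familiar, the second half unfamiliar).
#' @param n_presentations Presentations per stimulus (default 2).
#' @param trial_duration,epoch_duration Seconds; the trial must be an integer
#'   multiple of the epoch (defaults 60 and 30).
#' @param n_channels EEG channels (default 21).
#' @param fs Analysis sampling rate, Hz (default 64).
#' @param snr_map Tibble with columns `familiarity` ("familiar"/"unfamiliar"),
#'   `mw_group` ("low"/"high"), `snr` (> 0).
#' @param subject_sd,stimulus_sd SDs (log scale) of the multiplicative
#'   per-subject and per-stimulus SNR random effects.
#' @param p_answer_familiar_given_familiar,p_answer_unfamiliar_given_unfamiliar
#'   First-presentation answer accuracies (defaults 0.80 and 0.67).
#' @param mw_propensity_sd Spread (logit scale) of the per-subject latent
#'   mind-wandering propensity around its group centre.
#' @param seed Integer seed; identical config and seed give identical studies.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects,
                       n_stimuli = 8L,
                       n_presentations = 2L,
                       trial_duration = 60,
                       epoch_duration = 30,
                       n_channels = 21L,
                       fs = 64,
                       snr_map = default_snr_map(),
                       subject_sd = 0.25,
                       stimulus_sd = 0.15,
                       p_answer_familiar_given_familiar = 0.80,
                       p_answer_unfamiliar_given_unfamiliar = 0.67,
                       mw_propensity_sd = 0.5,
                       seed = 1L) {
  probs <- c(p_answer_familiar_given_familiar,
             p_answer_unfamiliar_given_unfamiliar)
  if (any(probs < 0 | probs > 1)) abort("answer probabilities must be in [0, 1].")
  if (any(c(subject_sd, stimulus_sd, mw_propensity_sd) < 0)) {
    abort("standard deviations must be nonnegative.")
  }
  if (any(c(n_subjects, n_stimuli, n_presentations, n_channels,
            trial_duration, epoch_duration, fs) <= 0)) {
    abort("counts, durations and fs must be positive.")
  }
  if (abs(trial_duration / epoch_duration -
          round(trial_duration / epoch_duration)) > 1e-9) {
    abort("`trial_duration` must be an integer multiple of `epoch_duration`.")
  }
  stopifnot(all(c("familiarity", "mw_group", "snr") %in% names(snr_map)))
  if (any(snr_map$snr <= 0)) abort("all snr_map values must be positive.")
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_stimuli = as.integer(n_stimuli),
         n_presentations = as.integer(n_presentations),
         trial_duration = trial_duration, epoch_duration = epoch_duration,
         n_channels = as.integer(n_channels), fs = fs, snr_map = snr_map,
         subject_sd = subject_sd, stimulus_sd = stimulus_sd,
         p_answer_familiar_given_familiar = p_answer_familiar_given_familiar,
         p_answer_unfamiliar_given_unfamiliar = p_answer_unfamiliar_given_unfamiliar,
         mw_propensity_sd = mw_propensity_sd, seed = as.integer(seed)),
    class = "sim_config")
}

#' @rdname sim_config
#' @export
default_snr_map <- function() {
  tibble(
    familiarity = c("familiar", "unfamiliar", "familiar", "unfamiliar"),
    mw_group = c("low", "low", "high", "high"),
    snr = c(0.25, 0.25, 0.35, 0.22)
  )
}

#' @rdname sim_config
#' @param value Constant SNR used in every cell.
#' @export
flat_snr_map <- function(value = 0.25) {
  m <- default_snr_map()
  m$snr <- value
  m
}

#' Simulate a band-limited stimulus amplitude envelope
#'
#' Draws Gaussian noise, band-passes it to 1-9 Hz (the modulation band the
#' analysis operates in), offsets and rectifies it to be nonnegative — a
#' cochlear envelope cannot go below zero — and low-passes at 9 Hz to remove
#' rectification harmonics. The result has its non-DC spectral power
#' concentrated in the 1-9 Hz band.
#'
#' @param duration Seconds.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @return Nonnegative numeric vector of `round(duration * fs)` samples.
#' @export
simulate_envelope <- function(duration, fs, seed) {
  if (duration <= 0 || fs <= 0) abort("`duration` and `fs` must be positive.")
  n <- round(duration * fs)
  if (n < 2) abort("need at least 2 samples.")
  set.seed(as.integer(seed))
  x <- rnorm(n)
  nyq <- fs / 2
  x <- signal::filtfilt(signal::butter(2, c(1, 9) / nyq, type = "pass"), x)
  x <- x + 2.5 * sd(x)
  x[x < 0] <- 0
  x <- signal::filtfilt(signal::butter(4, 9 / nyq, type = "low"), x)
  pmax(x, 0)
}

#' Simulate ground-truth forward kernels
#'
#' One causal finite impulse response per channel — a damped oscillation with
#' channel-specific frequency, decay, phase and amplitude (a random scalp
#' topography) — supported on 0-350 ms. Convolving the stimulus envelope with
#' these kernels produces the cortical tracking signal each channel carries.
#'
#' @param n_channels Number of EEG channels.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @return A `n_channels x n_lags` matrix (lags 0 .. 350 ms).
#' @export
simulate_kernels <- function(n_channels, fs, seed) {
  set.seed(as.integer(seed))
  n_lag <- floor(0.35 * fs) + 1L
  t_lag <- (seq_len(n_lag) - 1) / fs
  k <- matrix(0, n_channels, n_lag)
  for (ch in seq_len(n_channels)) {
    f <- runif(1, 2, 8)
    tau <- runif(1, 0.05, 0.15)
    phi <- runif(1, 0, 2 * pi)
    amp <- rnorm(1)
    k[ch, ] <- amp * exp(-t_lag / tau) * sin(2 * pi * f * t_lag + phi)
  }
  k
}

#' Simulate one EEG epoch from an envelope
#'
#' Forward model: each channel is the causal convolution of the stimulus
#' envelope with that channel's kernel, plus 1/f-shaped noise band-limited to
#' 1-9 Hz and scaled so the channel-wise RMS signal-to-noise ratio equals
#' `snr`. `snr = Inf` gives noise-free data; a zero envelope gives pure noise.
#'
#' @param envelope Numeric vector, the stimulus envelope at `fs`.
#' @param kernels Channels-by-lags matrix from [simulate_kernels()].
#' @param snr Positive linear-amplitude signal-to-noise ratio (may be `Inf`).
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @return A channels-by-time matrix.
#' @export
simulate_eeg <- function(envelope, kernels, snr, fs, seed) {
  if (!(snr > 0)) abort("`snr` must be positive.")
  n <- length(envelope)
  n_ch <- nrow(kernels)
  if (ncol(kernels) > n) abort("kernel support exceeds the envelope length.")
  set.seed(as.integer(seed))
  env_c <- envelope - mean(envelope)
  sig <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    full <- convolve(env_c, rev(kernels[ch, ]), type = "open")
    sig[ch, ] <- full[seq_len(n)]
  }
  if (!is.finite(snr)) return(sig)
  out <- sig
  nyq <- fs / 2
  bf <- signal::butter(2, c(1, 9) / nyq, type = "pass")
  for (ch in seq_len(n_ch)) {
    noise <- one_over_f_noise(n, fs)
    noise <- signal::filtfilt(bf, noise)
    rms_n <- sqrt(mean(noise^2))
    rms_s <- sqrt(mean(sig[ch, ]^2))
    target <- if (rms_s > 0) rms_s / snr else 1
    out[ch, ] <- sig[ch, ] + noise * target / rms_n
  }
  out
}

# Noise with power spectral density ~ 1/f (amplitude ~ f^-1/2), flat below 1 Hz.
one_over_f_noise <- function(n, fs) {
  white <- rnorm(n)
  X <- fft(white)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)            # two-sided frequency axis
  shape <- 1 / sqrt(pmax(f, 1))
  Re(fft(X * shape, inverse = TRUE) / n)
}

#' Simulate a complete synthetic study
#'
#' Generates one 60-s envelope per stimulus, forward-models every trial's EEG
#' at its cell SNR (scaled by the subject's and stimulus's multiplicative
#' random effects), cuts both modalities into aligned epochs, and draws the
#' per-trial questionnaire answers: first-presentation familiarity answers
#' match the designed label with the configured probabilities (misses split
#' 2:1 between "No" and "Not sure" for familiar stimuli, and go to "Yes" for
#' unfamiliar ones), and each trial's mind-wandering bin is the subject's
#' latent propensity plus trial noise, cut at 25/50/75%.
#'
#' @param config A [sim_config()].
#' @return A list with `trials` — a tibble with one row per epoch
#'   (`subject_id`, `stimulus_id`, `presentation`, `epoch_index`,
#'   `familiarity_answer`, `mw_answer_bin`, `snr`, and list-columns
#'   `envelope`, `eeg`) — and `truth` (kernels, designed familiarity, true
#'   mind-wandering groups, subject/stimulus SNR effects).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n_half <- ceiling(cfg$n_stimuli / 2)
  designed <- tibble(
    stimulus_id = seq_len(cfg$n_stimuli),
    designed_familiarity = ifelse(seq_len(cfg$n_stimuli) <= n_half,
                                  "familiar", "unfamiliar"),
    stimulus_effect = exp(rnorm(cfg$n_stimuli, 0, cfg$stimulus_sd))
  )
  mw_centre <- c(low = 0.25, high = 0.65)
  subjects <- tibble(
    subject_id = seq_len(cfg$n_subjects),
    true_mw_group = rep_len(c("low", "high"), cfg$n_subjects),
    subject_effect = exp(rnorm(cfg$n_subjects, 0, cfg$subject_sd))
  ) %>%
    mutate(mw_propensity = stats::plogis(
      stats::qlogis(mw_centre[.data$true_mw_group]) +
        rnorm(cfg$n_subjects, 0, cfg$mw_propensity_sd)))

  kernels <- simulate_kernels(cfg$n_channels, cfg$fs,
                              seed = derive_seed(cfg$seed, 7L))
  envelopes <- purrr::map(seq_len(cfg$n_stimuli), function(st) {
    simulate_envelope(cfg$trial_duration, cfg$fs,
                      seed = derive_seed(cfg$seed, 100L + st))
  })

  mw_bins <- c("0-25%", "25-50%", "50-75%", "75-100%")
  trial_grid <- tidyr::expand_grid(
    subject_id = seq_len(cfg$n_subjects),
    stimulus_id = seq_len(cfg$n_stimuli),
    presentation = seq_len(cfg$n_presentations)
  ) %>%
    left_join(subjects, by = "subject_id") %>%
    left_join(designed, by = "stimulus_id")

  set.seed(derive_seed(cfg$seed, 11L))
  trial_grid <- trial_grid %>%
    mutate(
      snr = .data$subject_effect * .data$stimulus_effect *
        snr_lookup(cfg$snr_map, .data$designed_familiarity, .data$true_mw_group),
      familiarity_answer = draw_familiarity_answer(
        .data$designed_familiarity,
        cfg$p_answer_familiar_given_familiar,
        cfg$p_answer_unfamiliar_given_unfamiliar),
      mw_value = pmin(pmax(.data$mw_propensity +
                             rnorm(dplyr::n(), 0, 0.15), 0), 1 - 1e-9),
      mw_answer_bin = mw_bins[findInterval(.data$mw_value,
                                           c(0, 0.25, 0.5, 0.75))]
    )

  trials <- purrr::pmap(
    list(trial_grid$subject_id, trial_grid$stimulus_id,
         trial_grid$presentation, trial_grid$snr),
    function(su, st, pr, snr) {
      eeg <- simulate_eeg(envelopes[[st]], kernels, snr, cfg$fs,
                          seed = derive_seed(cfg$seed,
                                             su * 10000L + st * 100L + pr))
      ep_env <- epoch_trace(envelopes[[st]], cfg$fs, cfg$epoch_duration)
      ep_eeg <- epoch_trace(eeg, cfg$fs, cfg$epoch_duration)
      tibble(epoch_index = ep_env$epoch_index,
             envelope = ep_env$data, eeg = ep_eeg$data)
    })
  out <- trial_grid %>%
    mutate(epochs = trials) %>%
    tidyr::unnest("epochs") %>%
    select("subject_id", "stimulus_id", "presentation", "epoch_index",
           "familiarity_answer", "mw_answer_bin", "snr", "envelope", "eeg")

  list(
    trials = out,
    truth = list(
      kernels = kernels,
      designed = designed %>% select("stimulus_id", "designed_familiarity"),
      subjects = subjects %>%
        select("subject_id", "true_mw_group", "mw_propensity"),
      per_trial_snr = trial_grid %>%
        select("subject_id", "stimulus_id", "presentation", "snr"),
      config = cfg
    )
  )
}

snr_lookup <- function(map, familiarity, mw_group) {
  key <- paste(map$familiarity, map$mw_group, sep = ".")
  vals <- setNames(map$snr, key)
  unname(vals[paste(familiarity, mw_group, sep = ".")])
}

draw_familiarity_answer <- function(designed, p_ff, p_uu) {
  n <- length(designed)
  u <- runif(n)
  miss_split <- runif(n)
  ifelse(designed == "familiar",
         ifelse(u < p_ff, "Yes",
                ifelse(miss_split < 2 / 3, "No", "NotSure")),
         ifelse(u < p_uu,
                ifelse(miss_split < 2 / 3, "No", "NotSure"),
                "Yes"))
}

# Bounded 32-bit seed derived from a base seed and a stream tag.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 1103) %% 2147483629)
}

#' Simulate reconstruction-accuracy records directly
#'
#' A lightweight generator on the accuracy scale: per-epoch reconstruction
#' accuracies are drawn from the crossed random-intercept model the inference
#' stage fits (subject and stimulus intercepts plus residual noise), with a
#' familiarity effect of chosen size per mind-wandering group and an optional
#' repetition effect. Used for power and type-I studies of model selection and
#' follow-up testing, where full EEG simulation would add nothing but run time
#' to the question being asked.
#'
#' First-presentation familiarity answers follow the designed labels with the
#' configured agreement probabilities, and the planted effect follows each
#' subject's own *coded* (answered) familiarity — excerpts are categorised by
#' individual responses, so familiarity varies within stimulus across
#' subjects. Mind-wandering bins are emitted deterministically per group
#' ("0-25%" low, "75-100%" high) so the coding stage recovers the designed
#' groups exactly.
#'
#' @param n_subjects,n_stimuli,n_presentations,epochs_per_trial Design sizes.
#' @param mu Grand-mean accuracy.
#' @param effect_high,effect_low Familiarity effect (answered-familiar minus
#'   answered-unfamiliar) within the high and low mind-wandering groups.
#' @param repetition_effect Second-minus-first presentation effect.
#' @param subject_sd,stimulus_sd,resid_sd Random-intercept and residual SDs.
#' @param p_answer_familiar_given_familiar,p_answer_unfamiliar_given_unfamiliar
#'   Answer agreement rates (defaults 0.80 and 0.67).
#' @param seed Integer seed.
#' @return A tibble of trial records ready for [code_indicators()].
#' @export
simulate_accuracy_records <- function(n_subjects, n_stimuli = 8L,
                                      n_presentations = 2L,
                                      epochs_per_trial = 2L,
                                      mu = 0.06,
                                      effect_high = 0, effect_low = 0,
                                      repetition_effect = 0,
                                      subject_sd = 0.025,
                                      stimulus_sd = 0.015,
                                      resid_sd = 0.08,
                                      p_answer_familiar_given_familiar = 0.80,
                                      p_answer_unfamiliar_given_unfamiliar = 0.67,
                                      seed = 1L) {
  set.seed(as.integer(seed))
  n_half <- ceiling(n_stimuli / 2)
  subj <- tibble(
    subject_id = seq_len(n_subjects),
    true_mw_group = rep_len(c("low", "high"), n_subjects),
    b_subj = rnorm(n_subjects, 0, subject_sd)
  )
  stim <- tibble(
    stimulus_id = seq_len(n_stimuli),
    designed_familiarity = ifelse(seq_len(n_stimuli) <= n_half,
                                  "familiar", "unfamiliar"),
    b_stim = rnorm(n_stimuli, 0, stimulus_sd)
  )
  answers <- tidyr::expand_grid(subject_id = seq_len(n_subjects),
                                stimulus_id = seq_len(n_stimuli)) %>%
    left_join(stim, by = "stimulus_id") %>%
    mutate(first_answer = draw_familiarity_answer(
      .data$designed_familiarity,
      p_answer_familiar_given_familiar,
      p_answer_unfamiliar_given_unfamiliar)) %>%
    select("subject_id", "stimulus_id", "first_answer")
  tidyr::expand_grid(subject_id = seq_len(n_subjects),
                     stimulus_id = seq_len(n_stimuli),
                     presentation = seq_len(n_presentations),
                     epoch_index = seq_len(epochs_per_trial)) %>%
    left_join(subj, by = "subject_id") %>%
    left_join(stim, by = "stimulus_id") %>%
    left_join(answers, by = c("subject_id", "stimulus_id")) %>%
    mutate(
      familiarity_answer = .data$first_answer,
      mw_answer_bin = ifelse(.data$true_mw_group == "high",
                             "75-100%", "0-25%"),
      effect = ifelse(.data$true_mw_group == "high", effect_high, effect_low),
      accuracy = mu + .data$b_subj + .data$b_stim +
        .data$effect * (.data$first_answer == "Yes") +
        repetition_effect * (.data$presentation == 2L) +
        rnorm(dplyr::n(), 0, resid_sd)
    ) %>%
    select("subject_id", "stimulus_id", "presentation", "epoch_index",
           "familiarity_answer", "mw_answer_bin", "accuracy")
}
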