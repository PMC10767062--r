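#' Nested leave-one-out stimulus reconstruction
#'
#' For each held-out epoch an outer leave-one-out (LOO) fold separates
#' training and test data; a second LOO nested inside the training set scores
#' every candidate ridge parameter by its mean inner-fold Pearson r, the best
#' `lambda` (ties broken toward more regularisation) is refit on all training
#' epochs jointly — lagged design matrices stacked, never bridging epoch
#' boundaries — and the refit model reconstructs the held-out epoch. A study
#' with 32 epochs per participant therefore yields 32 models and 32 accuracy
#' values per participant.
#'
#' EEG channels and envelopes are z-scored within each epoch before fitting
#' (Pearson accuracies are invariant to this). Per-epoch Gram matrices are
#' precomputed once so every inner and outer fold is a cheap downdate.
#'
#' @param epochs Tibble with list-columns `eeg` (channels x time matrices) and
#'   `envelope` (numeric vectors of matching length); any other columns are
#'   carried through as metadata.
#' @param t_min,t_max Decoding window bounds in seconds (defaults -0.2 and
#'   0.35, i.e. 36 sample shifts at 64 Hz).
#' @param fs Analysis sampling rate, Hz.
#' @param lambda_grid Candidate ridge penalties; default `10^(-6:6)`.
#' @param keep_models Keep each fold's `decoder_model` in a list-column.
#' @return The input tibble plus `lambda_selected`, `accuracy`, and
#'   list-columns `reconstruction` and (optionally) `model`.
#' @export
nested_loo_decode <- function(epochs, t_min = -0.2, t_max = 0.35, fs = 64,
                              lambda_grid = 10^(-6:6), keep_models = TRUE) {
  n <- nrow(epochs)
  if (n < 3) abort("need at least 3 epochs for nested leave-one-out.")
  if (length(lambda_grid) == 0) abort("`lambda_grid` must be non-empty.")
  lambda_grid <- sort(as.numeric(lambda_grid))
  lw <- lag_grid(t_min, t_max, fs)

  eeg <- purrr::map(epochs$eeg, zscore_rows)
  env <- purrr::map(epochs$envelope, zscore_vec)
  purrr::walk2(eeg, env, function(d, s) {
    if (ncol(d) != length(s)) abort("EEG and envelope epoch lengths differ.")
  })

  lagmat <- function(i) build_lagged_matrix(eeg[[i]], lw)
  gram <- vector("list", n); xty <- vector("list", n)
  for (i in seq_len(n)) {
    D <- lagmat(i)
    gram[[i]] <- crossprod(D)
    xty[[i]] <- crossprod(D, env[[i]])
  }
  A_tot <- Reduce(`+`, gram)
  b_tot <- Reduce(`+`, xty)

  lambda_selected <- numeric(n)
  accuracy <- numeric(n)
  recon <- vector("list", n)
  models <- vector("list", n)

  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    A_i <- A_tot - gram[[i]]
    b_i <- b_tot - xty[[i]]
    best <- if (length(lambda_grid) == 1L) {
      lambda_grid
    } else {
      inner_r <- matrix(NA_real_, length(train), length(lambda_grid))
      for (k in seq_along(train)) {
        j <- train[k]
        A_ij <- A_i - gram[[j]]
        b_ij <- b_i - xty[[j]]
        D_j <- lagmat(j)
        for (l in seq_along(lambda_grid)) {
          g <- ridge_solve(A_ij, b_ij, lambda_grid[l])
          inner_r[k, l] <- cor(drop(D_j %*% g), env[[j]])
        }
      }
      mean_r <- colMeans(inner_r)
      # ties toward larger lambda: last index among the maxima
      lambda_grid[max(which(mean_r >= max(mean_r) - 1e-12))]
    }
    g <- ridge_solve(A_i, b_i, best)
    model <- structure(list(g = g, lag_window = lw, lambda = best,
                            training_epochs = train),
                       class = "decoder_model")
    s_hat <- drop(lagmat(i) %*% g)
    lambda_selected[i] <- best
    accuracy[i] <- score_reconstruction(s_hat, env[[i]])
    recon[[i]] <- s_hat
    if (keep_models) models[[i]] <- model
  }

  out <- epochs %>%
    mutate(lambda_selected = lambda_selected, accuracy = accuracy,
           reconstruction = recon)
  if (keep_models) out$model <- models
  out
}

#' Decode every participant of a study
#'
#' Runs [nested_loo_decode()] separately within each subject (each subject's
#' epochs form one leave-one-out set) and binds the per-epoch results.
#'
#' @param trials Tibble of epochs with a `subject_id` column plus the columns
#'   [nested_loo_decode()] requires.
#' @inheritParams nested_loo_decode
#' @return One row per epoch with `lambda_selected` and `accuracy`.
#' @export
decode_study <- function(trials, t_min = -0.2, t_max = 0.35, fs = 64,
                         lambda_grid = 10^(-6:6), keep_models = FALSE) {
  stopifnot("subject_id" %in% names(trials))
  trials %>%
    group_by(.data$subject_id) %>%
    group_split() %>%
    purrr::map(nested_loo_decode, t_min = t_min, t_max = t_max, fs = fs,
               lambda_grid = lambda_grid, keep_models = keep_models) %>%
    bind_rows()
}

zscore_vec <- function(x) {
  s <- sd(x)
  if (s == 0) x - mean(x) else (x - mean(x)) / s
}

zscore_rows <- function(m) {
  t(apply(m, 1, zscore_vec))
}
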