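#' Integer lag grid for a backward decoding window
#'
#' The decoder maps EEG at lags \eqn{\tau} onto the stimulus sample at time
#' \eqn{t} via \eqn{d(t + \tau, n)}. Lags run over every integer sample shift
#' between `floor(t_min * fs)` and `floor(t_max * fs)` inclusive. Flooring
#' both bounds is the package's canonical rounding convention: the window
#' \[-0.2 s, +0.35 s\] at 64 Hz gives shifts -13 .. 22, i.e. 36 shifts
#' including zero.
#'
#' @param t_min,t_max Window bounds in seconds; negative values reach into
#'   pre-stimulus EEG.
#' @param fs Sampling rate, Hz.
#' @return A list of class `lag_window` with `t_min`, `t_max`, `fs`, and the
#'   integer `shifts`.
#' @examples
#' length(lag_grid(-0.2, 0.35, 64)$shifts)  # 36
#' @export
lag_grid <- function(t_min, t_max, fs) {
  if (t_min > t_max) abort("`t_min` must be <= `t_max`.")
  if (fs <= 0) abort("`fs` must be positive.")
  shifts <- seq.int(floor(t_min * fs), floor(t_max * fs))
  structure(list(t_min = t_min, t_max = t_max, fs = fs,
                 shifts = as.integer(shifts)),
            class = "lag_window")
}

#' Lagged design matrix
#'
#' Builds the time-by-(channels x lags) design matrix `D` whose column for
#' channel `n` and shift `tau` holds `d(t + tau, n)` at row `t`; samples
#' falling outside the epoch are zero-filled. Columns are ordered
#' channel-major: all shifts of channel 1, then all shifts of channel 2, and
#' so on. [reconstruct()] relies on this fixed ordering.
#'
#' @param eeg Channels-by-time numeric matrix for one epoch.
#' @param lag_window A [lag_grid()] result.
#' @return A `time x (channels * n_shifts)` matrix.
#' @export
build_lagged_matrix <- function(eeg, lag_window) {
  stopifnot(is.matrix(eeg), inherits(lag_window, "lag_window"))
  n_ch <- nrow(eeg); n_t <- ncol(eeg)
  shifts <- lag_window$shifts
  if (n_t < length(shifts)) abort("epoch shorter than the lag window.")
  D <- matrix(0, n_t, n_ch * length(shifts))
  for (ch in seq_len(n_ch)) {
    for (j in seq_along(shifts)) {
      src <- seq_len(n_t) + shifts[j]
      ok <- src >= 1L & src <= n_t
      D[ok, (ch - 1L) * length(shifts) + j] <- eeg[ch, src[ok]]
    }
  }
  D
}

#' Closed-form ridge regression fit
#'
#' Minimises \eqn{\sum_t (s(t) - \hat s(t))^2 + \lambda \lVert g \rVert^2} via
#' the normal equations \eqn{(D^\top D + \lambda I) g = D^\top s}, solved by
#' Cholesky factorisation rather than an explicit inverse. With `lambda = 0`
#' on a full-column-rank design this is the ordinary least-squares solution;
#' a rank-deficient design with `lambda = 0` falls back to the minimum-norm
#' solution (pseudo-inverse) with a warning.
#'
#' @param D Design matrix (rows = time samples), e.g. from
#'   [build_lagged_matrix()], or a precomputed Gram pair via `gram`/`xty`.
#' @param s Response vector (stimulus envelope samples).
#' @param lambda Nonnegative ridge penalty.
#' @return Numeric coefficient vector `g` of length `ncol(D)`.
#' @export
ridge_fit <- function(D, s, lambda = 0) {
  if (!all(is.finite(D)) || !all(is.finite(s))) abort("non-finite inputs.")
  if (lambda < 0) abort("`lambda` must be nonnegative.")
  if (nrow(D) != length(s)) abort("rows of `D` must match length of `s`.")
  A <- crossprod(D)
  b <- crossprod(D, s)
  ridge_solve(A, b, lambda)
}

# Solve (A + lambda I) g = b for symmetric PSD A; minimum-norm fallback at
# lambda = 0 when A is numerically singular.
ridge_solve <- function(A, b, lambda) {
  p <- nrow(A)
  if (lambda == 0) {
    # unpenalised: detect (numerical) rank deficiency explicitly, since a
    # Cholesky factorisation can silently succeed on a singular Gram matrix
    e <- eigen(A, symmetric = TRUE)
    pos <- e$values > max(e$values, 0) * p * .Machine$double.eps * 100
    if (sum(pos) < p) {
      warn("rank-deficient design with lambda = 0; returning minimum-norm solution.")
      V <- e$vectors[, pos, drop = FALSE]
      return(drop(V %*% (crossprod(V, b) / e$values[pos])))
    }
  }
  ch <- tryCatch(chol(A + diag(lambda, p)), error = function(e) NULL)
  if (is.null(ch)) abort("ridge system could not be factorised.")
  drop(backsolve(ch, forwardsolve(t(ch), b)))
}

#' Reconstruct a stimulus envelope from an EEG epoch
#'
#' Applies a fitted backward model:
#' \eqn{\hat s(t) = \sum_n \sum_\tau d(t + \tau, n)\, g(\tau, n)}, i.e.
#' `D %*% g` with the channel-major column ordering of
#' [build_lagged_matrix()].
#'
#' @param eeg Channels-by-time matrix.
#' @param model A `decoder_model` from [nested_loo_decode()] or a plain list
#'   with elements `g` (coefficients) and `lag_window`.
#' @return Numeric vector, same length as the epoch.
#' @export
reconstruct <- function(eeg, model) {
  if (nrow(eeg) * length(model$lag_window$shifts) != length(model$g)) {
    abort("channel count does not match the fitted model.")
  }
  drop(build_lagged_matrix(eeg, model$lag_window) %*% model$g)
}

#' Reconstruction accuracy
#'
#' Pearson product-moment correlation between a reconstructed and an original
#' envelope; the score used throughout to quantify cortical tracking.
#'
#' @param reconstruction,original Equal-length numeric vectors.
#' @return Pearson r in \[-1, 1\].
#' @export
score_reconstruction <- function(reconstruction, original) {
  if (length(reconstruction) != length(original)) abort("length mismatch.")
  if (sd(reconstruction) == 0 || sd(original) == 0) {
    abort("correlation undefined for a constant trace.")
  }
  cor(reconstruction, original)
}
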