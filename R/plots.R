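#' Plot reconstruction accuracy by condition
#'
#' Small-point individual subject cell means with large-point group means and
#' standard-error bars, split by familiarity and (optionally) mind-wandering
#' group.
#'
#' @param records Coded records with `accuracy`.
#' @param by_mw Facet by mind-wandering group (default TRUE).
#' @return A ggplot object.
#' @export
plot_accuracy_by_condition <- function(records, by_mw = TRUE) {
  subj <- records %>%
    group_by(.data$subject_id, .data$coded_familiarity,
             .data$coded_mw_group) %>%
    summarise(subject_mean = mean(.data$accuracy), .groups = "drop")
  cells <- group_summary(records)
  p <- ggplot2::ggplot(subj, ggplot2::aes(x = .data$coded_familiarity,
                                          y = .data$subject_mean)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.4, size = 1) +
    ggplot2::geom_pointrange(
      data = cells,
      ggplot2::aes(y = .data$mean_r, ymin = .data$mean_r - .data$sem,
                   ymax = .data$mean_r + .data$sem),
      size = 0.8, colour = "firebrick") +
    ggplot2::labs(x = "Familiarity", y = "Reconstruction accuracy (r)") +
    ggplot2::theme_minimal()
  if (by_mw) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$coded_mw_group),
                                 labeller = ggplot2::label_both)
  }
  p
}

#' Overlay a reconstructed envelope on the original
#'
#' @param decoded One row (or a subset) of a [nested_loo_decode()] result.
#' @param epoch Which row to plot (default 1).
#' @param fs Sampling rate for the time axis, Hz.
#' @return A ggplot object.
#' @export
plot_reconstruction <- function(decoded, epoch = 1, fs = 64) {
  s <- zscore_vec(decoded$envelope[[epoch]])
  s_hat <- zscore_vec(decoded$reconstruction[[epoch]])
  m <- min(length(s), length(s_hat))
  df <- tibble(
    t = rep((seq_len(m) - 1) / fs, 2),
    value = c(s[seq_len(m)], s_hat[seq_len(m)]),
    trace = rep(c("original", "reconstructed"), each = m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$trace)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "Time (s)", y = "Envelope (z)",
                  subtitle = sprintf("r = %.3f", decoded$accuracy[[epoch]])) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fitted tracking mixed model
#'
#' Forest-style plot of fixed-effect estimates with 95% confidence intervals.
#'
#' @param object A `tracking_lmm` from [fit_lmm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tracking_lmm
#' @export
autoplot.tracking_lmm <- function(object, ...) {
  df <- object$coefficients %>% filter(.data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(x = "Estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
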