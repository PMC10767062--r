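#' Mismatched-pairing null distribution of reconstruction accuracy
#'
#' For each subject, every reconstructed envelope is correlated against the
#' original envelopes of *other* (non-matching) epochs; a random derangement
#' of the epoch pairing is drawn per permutation, so a reconstruction is never
#' scored against its own stimulus. Averaging over epochs and permutations
#' gives one null accuracy per subject — the chance level against which the
#' observed per-subject mean accuracy is tested.
#'
#' @param results Decode results (from [decode_study()] /
#'   [nested_loo_decode()]) with `subject_id` and list-columns
#'   `reconstruction` and `envelope`.
#' @param n_permutations Number of random derangements per subject.
#' @param seed Integer seed.
#' @return A tibble with `subject_id`, `observed_mean_r`, `null_mean_r`,
#'   `n_epochs`.
#' @export
null_distribution <- function(results, n_permutations = 100, seed = 1L) {
  stopifnot(all(c("subject_id", "reconstruction", "envelope", "accuracy")
                %in% names(results)))
  set.seed(as.integer(seed))
  results %>%
    group_by(.data$subject_id) %>%
    group_split() %>%
    purrr::map(function(sub) {
      e <- nrow(sub)
      if (e < 2) abort("need >= 2 epochs per subject for a mismatched null.")
      # two epochs carrying the same envelope content (same stimulus and
      # epoch index, e.g. the other presentation) are not a valid mismatch
      key <- if (all(c("stimulus_id", "epoch_index") %in% names(sub))) {
        paste(sub$stimulus_id, sub$epoch_index)
      } else {
        as.character(seq_len(e))
      }
      vals <- numeric(n_permutations)
      for (p in seq_len(n_permutations)) {
        perm <- derangement(e, key)
        vals[p] <- mean(purrr::map_dbl(seq_len(e), function(i) {
          a <- sub$reconstruction[[i]]
          b <- sub$envelope[[perm[i]]]
          m <- min(length(a), length(b))
          cor(a[seq_len(m)], b[seq_len(m)])
        }))
      }
      tibble(subject_id = sub$subject_id[1],
             observed_mean_r = mean(sub$accuracy),
             null_mean_r = mean(vals),
             n_epochs = e)
    }) %>%
    bind_rows()
}

# Random permutation mapping no epoch to one with the same key (rejection
# sampling; keys identify envelope content, so self-pairs never occur).
derangement <- function(n, key = as.character(seq_len(n))) {
  for (try in seq_len(10000L)) {
    p <- sample.int(n)
    if (!any(key[p] == key)) return(p)
  }
  abort("could not draw a mismatched pairing; too many identical envelopes.")
}

#' Compare observed accuracy to its null distribution
#'
#' Paired one-sample t-test of the per-subject differences (observed minus
#' null mean accuracy), with Cohen's d = mean(difference) / sd(difference).
#'
#' @param null_table Output of [null_distribution()], or any tibble with
#'   `observed_mean_r` and `null_mean_r` per subject.
#' @return A one-row tibble: `observed_mean_r`, `null_mean_r`, `t_statistic`,
#'   `dof`, `p_value`, `cohens_d`, `n_subjects`.
#' @export
compare_to_null <- function(null_table) {
  d <- null_table$observed_mean_r - null_table$null_mean_r
  if (length(d) < 2) abort("need at least 2 subjects.")
  if (sd(d) == 0) abort("zero variance of differences; statistic undefined.")
  tt <- t.test(d)
  tibble(
    observed_mean_r = mean(null_table$observed_mean_r),
    null_mean_r = mean(null_table$null_mean_r),
    t_statistic = unname(tt$statistic),
    dof = unname(tt$parameter),
    p_value = tt$p.value,
    cohens_d = mean(d) / sd(d),
    n_subjects = length(d)
  )
}
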