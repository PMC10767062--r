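#' Code the familiarity indicator
#'
#' Two categories across stimuli: "High" when the answer to *Do you know this
#' music?* is "Yes", "Low" when it is "No" or "NotSure". Because each excerpt
#' is presented twice, only the first-presentation answer is used — avoiding a
#' repetition bias — and the code propagates to the second presentation's
#' epochs of the same (subject, stimulus).
#'
#' @param records Tibble with `subject_id`, `stimulus_id`, `presentation`
#'   (1 or 2) and `familiarity_answer` in `{"Yes", "No", "NotSure"}`.
#' @return `records` with a `coded_familiarity` factor (levels Low, High).
#' @export
code_familiarity <- function(records) {
  need <- c("subject_id", "stimulus_id", "presentation", "familiarity_answer")
  stopifnot(all(need %in% names(records)))
  bad <- setdiff(unique(records$familiarity_answer),
                 c("Yes", "No", "NotSure"))
  if (length(bad)) abort(paste("unknown familiarity answer:", bad[1]))
  first <- records %>%
    filter(.data$presentation == 1L) %>%
    distinct(.data$subject_id, .data$stimulus_id, .data$familiarity_answer) %>%
    mutate(coded_familiarity = factor(
      ifelse(.data$familiarity_answer == "Yes", "High", "Low"),
      levels = c("Low", "High"))) %>%
    select("subject_id", "stimulus_id", "coded_familiarity")
  missing <- records %>%
    distinct(.data$subject_id, .data$stimulus_id) %>%
    dplyr::anti_join(first, by = c("subject_id", "stimulus_id"))
  if (nrow(missing) > 0) {
    abort("missing first-presentation familiarity answer; cannot code.")
  }
  records %>%
    select(-dplyr::any_of("coded_familiarity")) %>%
    left_join(first, by = c("subject_id", "stimulus_id"))
}

mw_bin_midpoints <- c("0-25%" = 12.5, "25-50%" = 37.5,
                      "50-75%" = 62.5, "75-100%" = 87.5)

#' Code the mind-wandering indicator
#'
#' Two categories across participants. Each per-trial answer bin maps to its
#' midpoint percentage (12.5, 37.5, 62.5, 87.5); each subject's answers are
#' averaged; the grand mean is the mean of the subject means; a subject is
#' coded "High" when their mean exceeds the grand mean, otherwise "Low" (a
#' subject exactly at the grand mean is coded Low).
#'
#' @param records Tibble with `subject_id` and `mw_answer_bin` in
#'   `{"0-25%", "25-50%", "50-75%", "75-100%"}`.
#' @return `records` with a `coded_mw_group` factor (levels Low, High) and a
#'   `mw_subject_mean` column.
#' @export
code_mind_wandering <- function(records) {
  stopifnot(all(c("subject_id", "mw_answer_bin") %in% names(records)))
  bad <- setdiff(unique(records$mw_answer_bin), names(mw_bin_midpoints))
  if (length(bad)) abort(paste("unknown mind-wandering bin:", bad[1]))
  per_subject <- records %>%
    mutate(mw_mid = mw_bin_midpoints[.data$mw_answer_bin]) %>%
    group_by(.data$subject_id) %>%
    summarise(mw_subject_mean = mean(.data$mw_mid), .groups = "drop")
  grand <- mean(per_subject$mw_subject_mean)
  per_subject <- per_subject %>%
    mutate(coded_mw_group = factor(
      ifelse(.data$mw_subject_mean > grand, "High", "Low"),
      levels = c("Low", "High")))
  records %>%
    select(-dplyr::any_of(c("coded_mw_group", "mw_subject_mean"))) %>%
    left_join(per_subject, by = "subject_id")
}

#' Code the repetition indicator
#'
#' "First" for presentation 1, "Second" for presentation 2.
#'
#' @param records Tibble with a `presentation` column in `{1, 2}`.
#' @return `records` with a `coded_repetition` factor (levels First, Second).
#' @export
code_repetition <- function(records) {
  stopifnot("presentation" %in% names(records))
  if (!all(records$presentation %in% c(1L, 2L))) {
    abort("`presentation` must be 1 or 2.")
  }
  records %>%
    select(-dplyr::any_of("coded_repetition")) %>%
    mutate(coded_repetition = factor(
      ifelse(.data$presentation == 1L, "First", "Second"),
      levels = c("First", "Second")))
}

#' Code all three behavioral indicators
#'
#' Convenience wrapper applying [code_familiarity()], [code_mind_wandering()]
#' and [code_repetition()]. Coding is deterministic and idempotent: recoding
#' an already coded table changes nothing.
#'
#' @param records A tibble of trial records.
#' @return The coded tibble.
#' @export
code_indicators <- function(records) {
  records %>% code_familiarity() %>% code_mind_wandering() %>%
    code_repetition()
}

#' Agreement between answers and designed familiarity
#'
#' Over first presentations, the rate at which participants answered
#' unfamiliar ("No"/"NotSure") for designed-unfamiliar stimuli and familiar
#' ("Yes") for designed-familiar stimuli.
#'
#' @param records Trial records with `familiarity_answer`.
#' @param designed Tibble with `stimulus_id` and `designed_familiarity`
#'   ("familiar"/"unfamiliar"), e.g. `truth$designed` from [simulate_study()].
#' @return A tibble with one row per designed category: `designed_familiarity`,
#'   `n_answers`, `agreement` (proportion).
#' @export
familiarity_agreement <- function(records, designed) {
  records %>%
    filter(.data$presentation == 1L) %>%
    distinct(.data$subject_id, .data$stimulus_id, .data$familiarity_answer) %>%
    left_join(designed, by = "stimulus_id") %>%
    mutate(agrees = ifelse(.data$designed_familiarity == "familiar",
                           .data$familiarity_answer == "Yes",
                           .data$familiarity_answer %in% c("No", "NotSure"))) %>%
    group_by(.data$designed_familiarity) %>%
    summarise(n_answers = dplyr::n(), agreement = mean(.data$agrees),
              .groups = "drop")
}
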