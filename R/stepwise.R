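#' Stepwise backward reduction of the full mixed model
#'
#' Starts from the full model (all fixed terms and their interactions, plus
#' Subject and Stimulus random intercepts) and reduces it in two phases,
#' emitting the full elimination trace:
#'
#' * **Random phase** — each random intercept is tested by a likelihood-ratio
#'   test against the model without it (REML fits; identical fixed effects).
#'   Intercepts with p >= `alpha_random` are eliminated, largest p first.
#' * **Fixed phase** — repeatedly, the currently droppable fixed terms (those
#'   not marginal to a retained higher-order interaction) are tested by F
#'   tests with Satterthwaite denominator degrees of freedom; the term with
#'   the largest p >= `alpha_fixed` is eliminated and the model refit, until
#'   every remaining term is significant.
#'
#' @param records Coded trial records (or an [lmm_frame()] tibble).
#' @param formula Full fixed-effects formula; default the three-indicator
#'   factorial `Reconstruction ~ Familiarity * MindWandering * Repetition`.
#' @param random Random-intercept grouping factors.
#' @param alpha_random,alpha_fixed Retention thresholds (defaults 0.1, 0.05).
#' @return A list of class `stepwise_lmm`: `reduced_formula`, `elimination`
#'   (tibble with a `section` column, "random" / "fixed", in the layout of a
#'   backward-elimination summary table), and `fit` — the reduced model as a
#'   [fit_lmm()] object.
#' @export
stepwise_backward <- function(records,
                              formula = Reconstruction ~
                                Familiarity * MindWandering * Repetition,
                              random = c("Subject", "Stimulus"),
                              alpha_random = 0.1, alpha_fixed = 0.05) {
  frame <- if ("Reconstruction" %in% names(records)) records else
    lmm_frame(records)
  fixed_rhs <- paste(deparse(formula[[3]]), collapse = " ")
  resp <- deparse(formula[[2]])

  # ---- random phase ------------------------------------------------------
  kept_random <- random
  random_rows <- list()
  step_no <- 0L
  repeat {
    if (length(kept_random) == 0) break
    full_f <- build_formula(resp, fixed_rhs, kept_random)
    fit_full <- fit_mixed(full_f, frame, reml = TRUE)
    ll_full <- logLik(fit_full)
    stats_tbl <- purrr::map_dfr(kept_random, function(g) {
      red_f <- build_formula(resp, fixed_rhs, setdiff(kept_random, g))
      fit_red <- fit_mixed(red_f, frame, reml = TRUE)
      ll_red <- reml_loglik(fit_red)
      lrt <- max(0, 2 * (as.numeric(ll_full) - ll_red$value))
      tibble(term = paste0("(1 | ", g, ")"), group = g,
             npar = ll_red$npar, logLik = ll_red$value,
             AIC = -2 * ll_red$value + 2 * ll_red$npar,
             statistic = lrt, df = 1,
             p_value = pchisq(lrt, 1, lower.tail = FALSE))
    })
    worst <- stats_tbl %>% arrange(dplyr::desc(.data$p_value)) %>% head(1)
    if (worst$p_value >= alpha_random) {
      step_no <- step_no + 1L
      random_rows[[length(random_rows) + 1L]] <-
        worst %>% mutate(eliminated = step_no)
      kept_random <- setdiff(kept_random, worst$group)
    } else {
      random_rows[[length(random_rows) + 1L]] <-
        stats_tbl %>% mutate(eliminated = 0L)
      break
    }
  }
  random_tbl <- bind_rows(random_rows) %>%
    mutate(section = "random", .before = 1) %>%
    select("section", "term", "eliminated", "npar", "logLik", "AIC",
           "statistic", "df", "p_value")

  # ---- fixed phase -------------------------------------------------------
  current_rhs <- fixed_rhs
  fixed_rows <- list()
  fstep <- 0L
  repeat {
    f <- build_formula(resp, current_rhs, kept_random)
    fit <- fit_mixed(f, frame, reml = TRUE)
    dt <- drop_table(fit)
    if (nrow(dt) == 0) break
    worst <- dt %>% arrange(dplyr::desc(.data$p_value)) %>% head(1)
    if (worst$p_value >= alpha_fixed) {
      fstep <- fstep + 1L
      fixed_rows[[length(fixed_rows) + 1L]] <-
        worst %>% mutate(eliminated = fstep)
      current_rhs <- drop_term_rhs(f, worst$term)
      if (identical(current_rhs, "1")) break
    } else {
      fixed_rows[[length(fixed_rows) + 1L]] <- dt %>% mutate(eliminated = 0L)
      break
    }
  }
  fixed_tbl <- if (length(fixed_rows)) {
    bind_rows(fixed_rows) %>%
      mutate(section = "fixed", .before = 1) %>%
      select("section", "term", "eliminated", dplyr::any_of(
        c("sum_sq", "mean_sq", "num_df", "den_df")),
        "statistic", "p_value")
  } else {
    tibble(section = character(), term = character(),
           eliminated = integer(), statistic = numeric(),
           p_value = numeric())
  }

  reduced_formula <- build_formula(resp, current_rhs, kept_random)
  elimination <- bind_rows(random_tbl, fixed_tbl)
  reduced_fit <- fit_lmm(frame,
                         formula = as.formula(paste(resp, "~", current_rhs)),
                         random = kept_random)
  structure(list(reduced_formula = reduced_formula,
                 elimination = elimination,
                 fit = reduced_fit,
                 alpha_random = alpha_random, alpha_fixed = alpha_fixed),
            class = "stepwise_lmm")
}

# REML log-likelihood on lme4's convention (includes log|X'X|), so a model
# with no random effects stays comparable to an lmer REML fit with the same
# fixed effects. logLik.lm would return the ML value.
reml_loglik <- function(fit) {
  if (inherits(fit, "merMod")) {
    ll <- logLik(fit)
    return(list(value = as.numeric(ll), npar = attr(ll, "df")))
  }
  X <- stats::model.matrix(fit)
  n <- nrow(X); p <- ncol(X)
  rss <- sum(stats::resid(fit)^2)
  s2 <- rss / (n - p)
  val <- -0.5 * ((n - p) * log(2 * pi * s2) + (n - p) +
                   as.numeric(determinant(crossprod(X))$modulus))
  list(value = val, npar = p + 1L)
}

build_formula <- function(resp, rhs, random) {
  re <- if (length(random)) {
    paste("+", paste(sprintf("(1 | %s)", random), collapse = " + "))
  } else ""
  as.formula(paste(resp, "~", rhs, re), env = globalenv())
}

# Satterthwaite F tests (or plain F for lm) for the currently droppable
# terms, respecting marginality.
drop_table <- function(fit) {
  if (inherits(fit, "lmerModLmerTest")) {
    d <- suppressMessages(drop1(fit, ddf = "Satterthwaite"))
    d <- as.data.frame(d)
    if (nrow(d) == 0) return(tibble())
    tibble(term = rownames(d), sum_sq = d[["Sum Sq"]],
           mean_sq = d[["Mean Sq"]], num_df = d[["NumDF"]],
           den_df = d[["DenDF"]], statistic = d[["F value"]],
           p_value = d[["Pr(>F)"]])
  } else {
    d <- as.data.frame(drop1(fit, test = "F"))
    d <- d[rownames(d) != "<none>", , drop = FALSE]
    if (nrow(d) == 0) return(tibble())
    tibble(term = rownames(d), sum_sq = d[["Sum of Sq"]],
           mean_sq = d[["Sum of Sq"]] / d[["Df"]], num_df = d[["Df"]],
           den_df = stats::df.residual(fit), statistic = d[["F value"]],
           p_value = d[["Pr(>F)"]])
  }
}

# Remove one term from a fitted model's fixed part and return the new RHS
# (random terms excluded).
drop_term_rhs <- function(formula, term) {
  tt <- terms(lme4::nobars(formula))
  labs <- attr(tt, "term.labels")
  keep <- setdiff(labs, term)
  if (length(keep) == 0) "1" else paste(keep, collapse = " + ")
}

#' @export
print.stepwise_lmm <- function(x, ...) {
  cat("Stepwise backward reduction\n")
  cat("  reduced model:", deparse(x$reduced_formula), "\n")
  cat(sprintf("  alpha_random = %g, alpha_fixed = %g\n",
              x$alpha_random, x$alpha_fixed))
  print(x$elimination, n = Inf)
  invisible(x)
}

#' Fixed terms retained by a stepwise reduction
#'
#' @param x A `stepwise_lmm` object.
#' @return Character vector of fixed-effect term labels in the reduced model.
#' @export
retained_fixed_terms <- function(x) {
  attr(terms(lme4::nobars(x$reduced_formula)), "term.labels")
}

#' Random intercepts retained by a stepwise reduction
#'
#' @param x A `stepwise_lmm` object.
#' @return Character vector of grouping-factor names.
#' @export
retained_random_terms <- function(x) {
  bars <- lme4::findbars(x$reduced_formula)
  vapply(bars, function(b) deparse(b[[3]]), character(1))
}

#' Follow-up models within each level of a splitting factor
#'
#' Fits the inner model separately on the subsets defined by each level of
#' `split_factor` (default the mind-wandering group), the standard follow-up
#' when a factorial model hints at an interaction.
#'
#' @param records Coded trial records.
#' @param formula Inner fixed-effects formula (default
#'   `Reconstruction ~ Familiarity`).
#' @param split_factor Name of the modelling variable to split on.
#' @param random Random-intercept grouping factors.
#' @return A list of class `followup_lmm`: `fits` (named list of
#'   `tracking_lmm`) and `summary` — a tibble of the inner model's
#'   coefficients per level.
#' @export
follow_up_by_level <- function(records,
                               formula = Reconstruction ~ Familiarity,
                               split_factor = "MindWandering",
                               random = c("Subject", "Stimulus")) {
  frame <- if ("Reconstruction" %in% names(records)) records else
    lmm_frame(records)
  levs <- levels(droplevels(factor(frame[[split_factor]])))
  fits <- purrr::map(levs, function(lv) {
    sub <- frame %>% filter(.data[[split_factor]] == lv) %>%
      mutate(across(c("Subject", "Stimulus"), droplevels))
    if (nrow(sub) == 0) abort(paste("empty level:", lv))
    fit_lmm(sub, formula = formula, random = random)
  })
  names(fits) <- levs
  summary <- purrr::imap_dfr(fits, function(f, lv) {
    tidy(f) %>% mutate(level = lv, .before = 1)
  })
  structure(list(fits = fits, summary = summary,
                 split_factor = split_factor),
            class = "followup_lmm")
}

#' @export
print.followup_lmm <- function(x, ...) {
  cat("Follow-up models by", x$split_factor, "level\n")
  print(x$summary, n = Inf)
  invisible(x)
}
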