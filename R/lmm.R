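#' Modelling frame for the group-level mixed model
#'
#' Renames coded trial records into the variables the inference stage models:
#' `Reconstruction` (the per-epoch accuracy), `Familiarity`, `MindWandering`,
#' `Repetition`, `Subject`, `Stimulus`.
#'
#' @param records Coded records (see [code_indicators()]) with an `accuracy`
#'   column.
#' @return A tibble with the six modelling variables.
#' @export
lmm_frame <- function(records) {
  need <- c("accuracy", "coded_familiarity", "coded_mw_group",
            "coded_repetition", "subject_id", "stimulus_id")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    abort(paste("records lack coded columns:", paste(missing, collapse = ", ")))
  }
  tibble(
    Reconstruction = records$accuracy,
    Familiarity = records$coded_familiarity,
    MindWandering = records$coded_mw_group,
    Repetition = records$coded_repetition,
    Subject = factor(records$subject_id),
    Stimulus = factor(records$stimulus_id)
  )
}

#' Fit a crossed random-intercepts linear mixed model
#'
#' Fits `Reconstruction ~ <fixed terms> + (1|Subject) + (1|Stimulus)` by
#' REML (through lme4/lmerTest), and reports for every fixed effect the
#' estimate, Wald-t p-value with Satterthwaite degrees of freedom, a 95%
#' Wald confidence interval, and a standardized coefficient obtained by
#' refitting the same model on the z-scored response with binary predictors
#' coded -0.5/+0.5. Marginal and conditional R-squared follow the
#' variance-partition definitions: marginal = var(fixed) / total and
#' conditional = (var(fixed) + var(random)) / total, with
#' total = var(fixed) + var(random) + residual variance.
#'
#' @param records Coded trial records (or an [lmm_frame()] tibble).
#' @param formula Fixed-effects formula in the modelling variables, e.g.
#'   `Reconstruction ~ Familiarity * MindWandering * Repetition`. The two
#'   random intercepts are appended automatically unless the formula already
#'   contains a random part.
#' @param random Character vector of random-intercept grouping factors
#'   (default `c("Subject", "Stimulus")`).
#' @param reml Fit by REML (default) or ML.
#' @return An object of class `tracking_lmm`; see [tidy.tracking_lmm()] and
#'   [glance.tracking_lmm()].
#' @export
fit_lmm <- function(records, formula = Reconstruction ~ Familiarity,
                    random = c("Subject", "Stimulus"), reml = TRUE) {
  frame <- if ("Reconstruction" %in% names(records)) {
    records
  } else {
    lmm_frame(records)
  }
  fml <- add_random(formula, random)
  fit <- fit_mixed(fml, frame, reml = reml)
  coefs <- coef_table(fit)
  std <- std_beta_table(fml, frame, reml = reml)
  coefs <- coefs %>%
    mutate(.term_base = base_term(.data$term)) %>%
    left_join(std, by = c(".term_base" = "term")) %>%
    select(-".term_base")
  r2 <- r2_nakagawa(fit, frame)
  vc <- varcomp_table(fit)
  structure(
    list(fit = fit, formula = fml, coefficients = coefs,
         random_variances = vc,
         r2_marginal = r2[["marginal"]], r2_conditional = r2[["conditional"]],
         loglik = as.numeric(logLik(fit)), aic = AIC(fit),
         sigma = get_sigma(fit), nobs = stats::nobs(fit), reml = reml),
    class = "tracking_lmm")
}

add_random <- function(formula, random) {
  rhs <- paste(deparse(formula[[3]]), collapse = " ")
  if (grepl("\\|", rhs) || length(random) == 0) return(formula)
  re <- paste(sprintf("(1 | %s)", random), collapse = " + ")
  as.formula(paste(deparse(formula[[2]]), "~", rhs, "+", re),
             env = environment(formula))
}

has_random <- function(formula) {
  grepl("\\|", paste(deparse(formula[[3]]), collapse = " "))
}

# lmer when a random part is present, lm otherwise (possible after backward
# elimination of both random intercepts).
fit_mixed <- function(formula, data, reml = TRUE) {
  if (has_random(formula)) {
    fit <- suppressMessages(
      lmerTest::lmer(formula, data = data, REML = reml,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular = "ignore")))
    if (lme4::isSingular(fit, tol = 1e-5)) {
      warn("singular fit: a random-intercept variance is estimated at 0.")
    }
    fit
  } else {
    stats::lm(formula, data = data)
  }
}

coef_table <- function(fit) {
  sm <- if (inherits(fit, "lmerModLmerTest")) {
    as.data.frame(summary(fit)$coefficients)
  } else {
    cf <- as.data.frame(summary(fit)$coefficients)
    cf$df <- stats::df.residual(fit)
    cf[, c(1, 2, 5, 3, 4)]
  }
  names(sm) <- c("estimate", "std_error", "df", "t_value", "p_value")
  tibble(term = rownames(sm)) %>%
    dplyr::bind_cols(as_tibble(sm)) %>%
    mutate(
      conf_low = .data$estimate - qt(0.975, .data$df) * .data$std_error,
      conf_high = .data$estimate + qt(0.975, .data$df) * .data$std_error
    )
}

# Standardized coefficients: z-scored response, binary factors as -0.5/+0.5.
std_beta_table <- function(formula, frame, reml = TRUE) {
  std <- frame
  resp <- deparse(formula[[2]])
  std[[resp]] <- as.numeric(scale(std[[resp]]))
  for (v in names(std)) {
    if (is.factor(std[[v]]) && nlevels(std[[v]]) == 2 &&
        !v %in% c("Subject", "Stimulus")) {
      std[[v]] <- ifelse(std[[v]] == levels(std[[v]])[2], 0.5, -0.5)
    }
  }
  sfit <- fit_mixed(formula, std, reml = reml)
  ct <- coef_table(sfit)
  term_map <- base_term(ct$term)
  tibble(term_base = term_map, std_beta = ct$estimate,
         std_conf_low = ct$conf_low, std_conf_high = ct$conf_high) %>%
    mutate(term = .data$term_base, .keep = "unused") -> out
  out
}

# Strip factor-level suffixes so standardized terms join the factor-coded
# coefficient names ("FamiliarityHigh" -> "Familiarity").
base_term <- function(terms) {
  out <- terms
  for (lev in c("High", "Second")) {
    out <- gsub(paste0("(Familiarity|MindWandering|Repetition)", lev),
                "\\1", out)
  }
  out
}

varcomp_table <- function(fit) {
  if (!inherits(fit, "merMod")) {
    return(tibble(group = "Residual", variance = summary(fit)$sigma^2))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  tibble(group = vc$grp, variance = vc$vcov)
}

get_sigma <- function(fit) {
  if (inherits(fit, "merMod")) stats::sigma(fit) else summary(fit)$sigma
}

# Variance-partition R2 for mixed models (fixed / fixed+random / total).
r2_nakagawa <- function(fit, frame) {
  if (inherits(fit, "merMod")) {
    X <- lme4::getME(fit, "X")
    var_f <- var(as.vector(X %*% lme4::fixef(fit)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_r <- sum(vc$vcov[vc$grp != "Residual"])
    var_e <- stats::sigma(fit)^2
  } else {
    var_f <- var(stats::fitted(fit))
    var_r <- 0
    var_e <- summary(fit)$sigma^2
  }
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' @export
print.tracking_lmm <- function(x, ...) {
  cat("Linear mixed model (crossed random intercepts)\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  REML: %s   logLik: %.2f   AIC: %.2f\n",
              x$reml, x$loglik, x$aic))
  cat(sprintf("  R2 marginal: %.4g   R2 conditional: %.4g\n",
              x$r2_marginal, x$r2_conditional))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Tidy a fitted tracking mixed model
#'
#' @param x A `tracking_lmm` from [fit_lmm()].
#' @param ... Unused.
#' @return A tibble with one row per fixed effect: estimate, standard error,
#'   Satterthwaite df, t, p, 95% CI, standardized beta and its CI.
#' @method tidy tracking_lmm
#' @export
tidy.tracking_lmm <- function(x, ...) x$coefficients

#' One-row model summary of a tracking mixed model
#'
#' @param x A `tracking_lmm` from [fit_lmm()].
#' @param ... Unused.
#' @return A one-row tibble: R-squared (marginal, conditional), random
#'   variances, sigma, log-likelihood, AIC, nobs.
#' @method glance tracking_lmm
#' @export
glance.tracking_lmm <- function(x, ...) {
  vc <- setNames(x$random_variances$variance,
                 paste0("var_", tolower(x$random_variances$group)))
  dplyr::bind_cols(
    tibble(r2_marginal = x$r2_marginal, r2_conditional = x$r2_conditional),
    as_tibble(as.list(vc)),
    tibble(sigma = x$sigma, loglik = x$loglik, aic = x$aic, nobs = x$nobs)
  )
}

#' Likelihood-ratio test between nested mixed models
#'
#' Both models are refit by maximum likelihood (fixed-effect comparisons are
#' invalid under REML) and 2 * (logLik full - logLik reduced) is referred to a
#' chi-square with degrees of freedom equal to the parameter-count difference.
#'
#' @param full,reduced `tracking_lmm` objects (the reduced model must be
#'   nested in the full one) fitted to the same data.
#' @return A one-row tibble: `chisq`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  f1 <- refit_ml(full)
  f0 <- refit_ml(reduced)
  ll1 <- logLik(f1); ll0 <- logLik(f0)
  df <- attr(ll1, "df") - attr(ll0, "df")
  if (df < 0) abort("`reduced` has more parameters than `full`; not nested.")
  chisq <- max(0, 2 * (as.numeric(ll1) - as.numeric(ll0)))
  tibble(chisq = chisq, df = df,
         p_value = if (df == 0) 1 else pchisq(chisq, df, lower.tail = FALSE))
}

refit_ml <- function(m) {
  fit <- if (inherits(m, "tracking_lmm")) m$fit else m
  if (inherits(fit, "merMod") && lme4::isREML(fit)) {
    lme4::refitML(fit)
  } else {
    fit
  }
}
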