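# Random-intercept mixed models on change scores, planned contrasts at the
# Bonferroni-corrected alpha, effect sizes, ICC, and change-vs-zero tests.
# Estimation is maximum likelihood via lme4; degrees of freedom for t tests
# are Satterthwaite approximations via lmerTest.

prepare_delta_factors <- function(data) {
  data$relevance <- factor(data$relevance,
                           levels = c("stepping", "non_stepping"))
  data$step <- factor(data$step, levels = c("step1", "step2"))
  data$participant <- factor(data$participant)
  if (anyNA(data$relevance) || anyNA(data$step)) {
    stop("relevance/step contain values outside the crossing cells",
         call. = FALSE)
  }
  data
}

#' Fit a random-intercept model to change scores
#'
#' Fits `outcome ~ relevance + step (+ relevance:step) + (1 | participant)`
#' by maximum likelihood, with treatment coding and referents `stepping` and
#' `step1`. Reports Wald 95% confidence intervals and Satterthwaite-df
#' p-values per fixed effect, the two variance components, the ICC
#' (intercept variance over total), marginal and conditional R-squared
#' (variance-partition definitions: fixed-effects variance over total, and
#' fixed plus intercept variance over total), AIC and log-likelihood.
#'
#' A singular fit (intercept variance estimated at zero) succeeds with a
#' warning.
#'
#' @param data Change-score tibble with `participant`, `relevance`, `step`
#'   and the outcome column; at least 2 participants with at least 2 cells
#'   each.
#' @param outcome Name of the outcome column.
#' @param include_interaction Include the relevance-by-step interaction?
#' @return A list of class `attention_fit`; elements include `model` (the
#'   underlying `lmerModLmerTest` object), `fixed` (per-term tibble),
#'   `intercept_variance`, `residual_variance`, `icc`, `r2_marginal`,
#'   `r2_conditional`, `aic`, `loglik`, `includes_interaction`.
#' @export
fit_random_intercept_model <- function(data, outcome = "delta_percent_correct",
                                       include_interaction = FALSE) {
  data <- prepare_delta_factors(data)
  stopifnot(outcome %in% names(data))
  if (nlevels(data$participant) < 2) {
    stop("at least 2 participants are required", call. = FALSE)
  }
  rhs <- if (include_interaction) "relevance * step" else "relevance + step"
  form <- stats::as.formula(paste(outcome, "~", rhs, "+ (1 | participant)"))
  ctrl <- lme4::lmerControl(
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  model <- lmerTest::lmer(form, data = data, REML = FALSE, control = ctrl)
  if (lme4::isSingular(model)) {
    warning("singular fit: random-intercept variance estimated at zero",
            call. = FALSE)
  }
  smry <- summary(model, ddf = "Satterthwaite")
  co <- smry$coefficients
  fixed <- tibble::tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    se = co[, "Std. Error"],
    df = co[, "df"],
    t = co[, "t value"],
    p = co[, "Pr(>|t|)"]
  )
  fixed$ci_lower <- fixed$estimate - stats::qt(0.975, fixed$df) * fixed$se
  fixed$ci_upper <- fixed$estimate + stats::qt(0.975, fixed$df) * fixed$se

  vc <- as.data.frame(lme4::VarCorr(model))
  tau2 <- vc$vcov[vc$grp == "participant"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  var_fixed <- stats::var(as.numeric(
    stats::model.matrix(model) %*% lme4::fixef(model)))
  total <- var_fixed + tau2 + sigma2

  structure(list(
    outcome = outcome,
    model = model,
    fixed = fixed,
    intercept_variance = tau2,
    residual_variance = sigma2,
    icc = icc_from_components(tau2, sigma2),
    r2_marginal = var_fixed / total,
    r2_conditional = (var_fixed + tau2) / total,
    aic = stats::AIC(model),
    loglik = as.numeric(stats::logLik(model)),
    n_obs = stats::nobs(model),
    n_participants = nlevels(data$participant),
    includes_interaction = include_interaction
  ), class = "attention_fit")
}

#' @export
print.attention_fit <- function(x, ...) {
  cat(sprintf("<attention_fit> %s ~ relevance %s step + (1 | participant), ML\n",
              x$outcome, ifelse(x$includes_interaction, "*", "+")))
  print(as.data.frame(x$fixed), digits = 4)
  cat(sprintf("  intercept var %.3f, residual var %.3f, ICC %.3f\n",
              x$intercept_variance, x$residual_variance, x$icc))
  cat(sprintf("  R2 marginal/conditional %.3f/%.3f, AIC %.1f\n",
              x$r2_marginal, x$r2_conditional, x$aic))
  invisible(x)
}

#' Intraclass correlation from variance components
#'
#' @param intercept_variance Between-participant (random-intercept) variance.
#' @param residual_variance Residual variance.
#' @return `intercept_variance / (intercept_variance + residual_variance)`.
#' @export
icc_from_components <- function(intercept_variance, residual_variance) {
  stopifnot(intercept_variance >= 0, residual_variance >= 0)
  intercept_variance / (intercept_variance + residual_variance)
}

#' Keep the interaction only if it is significant and improves fit
#'
#' The relevance-by-step interaction stays in the model only when its Wald
#' test is significant (p < 0.05) and the interaction model has the lower
#' AIC; otherwise the additive model is selected.
#'
#' @param fit_without,fit_with `attention_fit`s on identical data, additive
#'   and interaction respectively.
#' @return The selected `attention_fit`, with a `selection` element
#'   recording the decision.
#' @export
select_model <- function(fit_without, fit_with) {
  stopifnot(inherits(fit_without, "attention_fit"),
            inherits(fit_with, "attention_fit"),
            !fit_without$includes_interaction,
            fit_with$includes_interaction,
            fit_without$n_obs == fit_with$n_obs)
  int_row <- grepl(":", fit_with$fixed$term)
  p_int <- fit_with$fixed$p[int_row][1]
  better_aic <- fit_with$aic < fit_without$aic
  keep <- is.finite(p_int) && p_int < 0.05 && better_aic
  chosen <- if (keep) fit_with else fit_without
  chosen$selection <- list(interaction_p = p_int,
                           aic_with = fit_with$aic,
                           aic_without = fit_without$aic,
                           interaction_retained = keep)
  chosen
}

# L-vector of a crossing cell mean in fixed-effect coordinates.
cell_L <- function(fit, relevance, step) {
  terms <- fit$fixed$term
  L <- stats::setNames(numeric(length(terms)), terms)
  L["(Intercept)"] <- 1
  if (relevance == "non_stepping") L["relevancenon_stepping"] <- 1
  if (step == "step2") L["stepstep2"] <- 1
  int_term <- "relevancenon_stepping:stepstep2"
  if (int_term %in% terms && relevance == "non_stepping" && step == "step2") {
    L[int_term] <- 1
  }
  L
}

contrast_1d <- function(fit, L, level = 0.95) {
  res <- lmerTest::contest1D(fit$model, L, confint = TRUE, level = level,
                             ddf = "Satterthwaite")
  tibble::tibble(estimate = res$Estimate, se = res$`Std. Error`,
                 df = res$df, t = res$`t value`,
                 ci_lower = res$lower, ci_upper = res$upper,
                 p = res$`Pr(>|t|)`)
}

#' The four planned pairwise comparisons among crossing cells
#'
#' Model-based cell-mean differences of the first stepping location against
#' the second stepping location and both non-stepping locations, plus the
#' second stepping against the second non-stepping location, with standard
#' errors from the fixed-effect covariance, Satterthwaite df, and
#' significance evaluated at the Bonferroni-corrected alpha of 0.013.
#' Cohen's d divides each difference by the square root of the total
#' outcome variance (intercept + residual components).
#'
#' @param fit An `attention_fit`.
#' @param alpha Corrected significance level.
#' @return Tibble: `contrast`, `estimate`, `se`, `df`, `t`, `ci_lower`,
#'   `ci_upper`, `p`, `significant`, `cohens_d`.
#' @export
pairwise_contrasts <- function(fit, alpha = 0.013) {
  stopifnot(inherits(fit, "attention_fit"))
  cells <- list(
    c("stepping", "step1"), c("stepping", "step2"),
    c("non_stepping", "step1"), c("non_stepping", "step2")
  )
  pairs <- list(
    step1_stepping_vs_step2_stepping = c(1, 2),
    step1_stepping_vs_step1_nonstepping = c(1, 3),
    step1_stepping_vs_step2_nonstepping = c(1, 4),
    step2_stepping_vs_step2_nonstepping = c(2, 4)
  )
  sd_total <- sqrt(fit$intercept_variance + fit$residual_variance)
  rows <- lapply(names(pairs), function(nm) {
    idx <- pairs[[nm]]
    L <- cell_L(fit, cells[[idx[1]]][1], cells[[idx[1]]][2]) -
      cell_L(fit, cells[[idx[2]]][1], cells[[idx[2]]][2])
    out <- contrast_1d(fit, L)
    out$contrast <- nm
    out
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- out$p < alpha
  out$cohens_d <- out$estimate / sd_total
  out[, c("contrast", "estimate", "se", "df", "t", "ci_lower", "ci_upper",
          "p", "significant", "cohens_d")]
}

#' Model-based change-vs-zero test per crossing cell
#'
#' Estimates each relevance-by-step cell mean of the change score from the
#' fitted model (equivalent to refitting with that cell as the referent and
#' reading the intercept), with its 95% confidence interval; a cell whose
#' interval excludes zero differs from the stationary baseline (p < 0.05).
#' Cohen's d divides the estimate by the between-participant SD of the
#' cell's raw change scores.
#'
#' @param fit An `attention_fit`.
#' @param level Confidence level.
#' @return Tibble: `relevance`, `step`, `estimate`, `ci_lower`, `ci_upper`,
#'   `significant`, `cohens_d`.
#' @export
change_vs_zero <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "attention_fit"))
  frame <- stats::model.frame(fit$model)
  outcome_col <- names(frame)[1]
  cells <- tidyr::expand_grid(relevance = c("stepping", "non_stepping"),
                              step = c("step1", "step2"))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    L <- cell_L(fit, cells$relevance[i], cells$step[i])
    out <- contrast_1d(fit, L, level = level)
    sub <- frame[frame$relevance == cells$relevance[i] &
                   frame$step == cells$step[i], outcome_col]
    out$relevance <- cells$relevance[i]
    out$step <- cells$step[i]
    out$cell_sd <- stats::sd(sub)
    out
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- out$ci_lower > 0 | out$ci_upper < 0
  out$cohens_d <- out$estimate / out$cell_sd
  out[, c("relevance", "step", "estimate", "se", "df", "ci_lower",
          "ci_upper", "p", "significant", "cohens_d")]
}

#' Cohen's f-squared for a model and for a dropped fixed effect
#'
#' The model-level effect size is `f2 = R2m / (1 - R2m)` on the marginal
#' R-squared; the effect-level size compares nested fits,
#' `f2 = (R2m_full - R2m_reduced) / (1 - R2m_full)`. Conventional labels:
#' 0.02 small, 0.15 medium, 0.35 large.
#'
#' @param fit_full An `attention_fit`.
#' @param fit_reduced Optional nested `attention_fit` (same data, fewer
#'   fixed-effect terms).
#' @return List of class `effect_sizes`: `model_f2`, `model_label`, and when
#'   a reduced fit is given `effect_f2`, `effect_label`.
#' @export
effect_sizes <- function(fit_full, fit_reduced = NULL) {
  stopifnot(inherits(fit_full, "attention_fit"))
  f2_label <- function(f2) {
    if (f2 >= 0.35) "large" else if (f2 >= 0.15) "medium"
    else if (f2 >= 0.02) "small" else "negligible"
  }
  r2f <- fit_full$r2_marginal
  out <- list(model_f2 = r2f / (1 - r2f),
              model_label = f2_label(r2f / (1 - r2f)))
  if (!is.null(fit_reduced)) {
    stopifnot(inherits(fit_reduced, "attention_fit"))
    nested <- all(fit_reduced$fixed$term %in% fit_full$fixed$term) &&
      fit_reduced$n_obs == fit_full$n_obs &&
      nrow(fit_reduced$fixed) < nrow(fit_full$fixed)
    if (!nested) stop("fits are not nested on the same data", call. = FALSE)
    out$effect_f2 <- (r2f - fit_reduced$r2_marginal) / (1 - r2f)
    out$effect_label <- f2_label(out$effect_f2)
  }
  structure(out, class = "effect_sizes")
}

#' @export
print.effect_sizes <- function(x, ...) {
  cat(sprintf("<effect_sizes> model f2 = %.3f (%s)", x$model_f2,
              x$model_label))
  if (!is.null(x$effect_f2)) {
    cat(sprintf("; dropped-effect f2 = %.3f (%s)", x$effect_f2,
                x$effect_label))
  }
  cat("\n")
  invisible(x)
}

#' Fit, select and summarise the mixed model for one outcome
#'
#' Convenience wrapper: fits the additive and interaction models, applies
#' the selection rule, and computes contrasts and change-vs-zero tests on
#' the selected model.
#'
#' @inheritParams fit_random_intercept_model
#' @param alpha Corrected alpha for the planned contrasts.
#' @return List: `selected`, `fit_additive`, `fit_interaction`,
#'   `contrasts`, `change_vs_zero`, `effect_sizes`.
#' @export
analyse_outcome <- function(data, outcome = "delta_percent_correct",
                            alpha = 0.013) {
  fit0 <- fit_random_intercept_model(data, outcome,
                                     include_interaction = FALSE)
  fit1 <- fit_random_intercept_model(data, outcome,
                                     include_interaction = TRUE)
  sel <- select_model(fit0, fit1)
  list(
    selected = sel,
    fit_additive = fit0,
    fit_interaction = fit1,
    contrasts = pairwise_contrasts(sel, alpha = alpha),
    change_vs_zero = change_vs_zero(sel),
    effect_sizes = effect_sizes(sel)
  )
}
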