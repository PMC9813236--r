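test_that("ICC reproduces the variance-component arithmetic", {
  expect_equal(round(icc_from_components(6.344, 21.076), 3), 0.231)
  expect_equal(icc_from_components(0, 5), 0)
  expect_error(icc_from_components(-1, 5))
})

test_that("balanced-design contrasts equal ordinary cell-mean differences", {
  d <- make_delta_data(51, cell_means = c(-7, 1, -1, 2))
  fit <- fit_quiet(d, "y", include_interaction = TRUE)
  cm <- tapply(d$y, paste(d$relevance, d$step), mean)
  ct <- pairwise_contrasts(fit)
  manual <- c(
    cm[["stepping step1"]] - cm[["stepping step2"]],
    cm[["stepping step1"]] - cm[["non_stepping step1"]],
    cm[["stepping step1"]] - cm[["non_stepping step2"]],
    cm[["stepping step2"]] - cm[["non_stepping step2"]]
  )
  expect_equal(ct$estimate, unname(manual), tolerance = 1e-6)
  # change-vs-zero estimates are the raw cell means on balanced data
  cz <- change_vs_zero(fit)
  expect_equal(
    cz$estimate,
    as.numeric(cm[paste(cz$relevance, cz$step)]),
    tolerance = 1e-6
  )
})

test_that("null simulations are unbiased with nominal CI coverage", {
  nrep <- 120
  hits <- matrix(NA, nrep, 3)
  ests <- matrix(NA, nrep, 3)
  for (r in seq_len(nrep)) {
    d <- make_delta_data(1000 + r)
    fit <- fit_quiet(d, "y")
    fx <- fit$fixed
    ests[r, ] <- fx$estimate
    hits[r, ] <- fx$ci_lower <= 0 & fx$ci_upper >= 0
  }
  expect_lt(max(abs(colMeans(ests))), 1.5)     # ~3 SE of the replicate mean
  coverage <- colMeans(hits)
  expect_true(all(coverage > 0.89 & coverage < 0.995))
})

test_that("model summaries expose ML variance components and R2", {
  d <- make_delta_data(52, cell_means = c(-7, 0, 0, 0))
  fit <- fit_quiet(d, "y")
  expect_false(fit$includes_interaction)
  expect_equal(fit$icc, fit$intercept_variance /
                 (fit$intercept_variance + fit$residual_variance))
  expect_gte(fit$r2_conditional, fit$r2_marginal)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 5)  # 3 fixed + 2 variances
  expect_equal(fit$n_obs, 48)
  # treatment coding with stepping/step1 referents
  expect_setequal(fit$fixed$term,
                  c("(Intercept)", "relevancenon_stepping", "stepstep2"))
})

test_that("interaction retention requires both significance and lower AIC", {
  # strong interaction: retained
  d_int <- make_delta_data(53, cell_means = c(0, 0, 0, 8))
  f1 <- fit_quiet(d_int, "y", include_interaction = TRUE)
  f0 <- fit_quiet(d_int, "y")
  sel <- select_quiet(f0, f1)
  expect_true(sel$selection$interaction_retained)
  expect_true(sel$includes_interaction)

  # null data: interaction p large in most draws -> dropped
  d_null <- make_delta_data(54)
  g1 <- fit_quiet(d_null, "y", include_interaction = TRUE)
  g0 <- fit_quiet(d_null, "y")
  sel0 <- select_quiet(g0, g1)
  p_int <- g1$fixed$p[grepl(":", g1$fixed$term)]
  if (p_int >= 0.05) expect_false(sel0$selection$interaction_retained)
  expect_equal(sel0$selection$interaction_retained,
               p_int < 0.05 && g1$aic < g0$aic)
})

test_that("a large true interaction is retained in most replicates", {
  retained <- vapply(1:60, function(s) {
    d <- make_delta_data(2000 + s, cell_means = c(0, 0, 0, 8))  # d ~ 1.5
    sel <- select_quiet(fit_quiet(d, "y"),
                        fit_quiet(d, "y", include_interaction = TRUE))
    sel$selection$interaction_retained
  }, TRUE)
  expect_gt(mean(retained), 0.75)
})

test_that("contrast machinery matches an independent emmeans computation", {
  skip_if_not_installed("emmeans")
  d <- make_delta_data(55, cell_means = c(-7, -1, 0, 2))
  fit <- fit_quiet(d, "y", include_interaction = TRUE)
  ct <- pairwise_contrasts(fit)
  em <- emmeans::emmeans(fit$model, ~ relevance * step,
                         lmer.df = "satterthwaite")
  prs <- summary(emmeans::contrast(em, method = list(
    c1 = c(1, 0, -1, 0),   # emmeans order: stepping/non_stepping x step1/step2
    c2 = c(1, -1, 0, 0),
    c3 = c(1, 0, 0, -1),
    c4 = c(0, 0, 1, -1)
  ), adjust = "none"), infer = TRUE)
  expect_equal(ct$estimate, prs$estimate, tolerance = 1e-6)
  expect_equal(ct$se, prs$SE, tolerance = 1e-6)
  expect_equal(ct$p, prs$p.value, tolerance = 1e-4)
})

test_that("contrast estimates are linear in the outcome scale", {
  d <- make_delta_data(56, cell_means = c(-5, 0, 0, 0))
  d2 <- d
  d2$y <- 2 * d$y
  c1 <- pairwise_contrasts(fit_quiet(d, "y", include_interaction = TRUE))
  c2 <- pairwise_contrasts(fit_quiet(d2, "y", include_interaction = TRUE))
  expect_equal(c2$estimate, 2 * c1$estimate, tolerance = 1e-6)
})

test_that("change-vs-zero flags respond to effects and respect symmetry", {
  # near-zero outcome: nothing flagged
  d0 <- make_delta_data(57, intercept_sd = 0.01, resid_sd = 0.01)
  cz0 <- change_vs_zero(fit_quiet(d0, "y"))
  expect_true(all(abs(cz0$estimate) < 0.02))
  expect_false(any(cz0$significant))

  # sign flip of all scores flips estimates, not flags
  d <- make_delta_data(58, cell_means = c(-9, 0, 0, 0))
  dneg <- d
  dneg$y <- -d$y
  a <- change_vs_zero(fit_quiet(d, "y", include_interaction = TRUE))
  b <- change_vs_zero(fit_quiet(dneg, "y", include_interaction = TRUE))
  expect_equal(a$estimate, -b$estimate, tolerance = 1e-6)
  expect_equal(a$significant, b$significant)
  expect_equal(a$cohens_d, -b$cohens_d, tolerance = 1e-6)
})

test_that("Cohen's f2 follows the marginal-R2 closed forms", {
  fake <- function(r2m) {
    structure(list(r2_marginal = r2m,
                   fixed = tibble::tibble(term = c("(Intercept)", "x")),
                   n_obs = 48), class = "attention_fit")
  }
  expect_equal(effect_sizes(fake(0.5))$model_f2, 1.0)
  f_full <- fake(0.205)
  expect_lt(abs(effect_sizes(f_full)$model_f2 - 0.260), 0.003)
  f_red <- fake(0.205)
  f_red$fixed <- f_red$fixed[1, ]
  es <- effect_sizes(f_full, f_red)
  expect_equal(es$effect_f2, 0)
  bad <- fake(0.3)
  bad$fixed <- tibble::tibble(term = c("(Intercept)", "z"))
  expect_error(effect_sizes(f_full, bad), "nested")
})

test_that("parameter recovery: generator effects resurface in the fit", {
  d <- simulate_delta_table(seed = 59)
  an <- suppressWarnings(analyse_outcome(d))
  fit <- an$fit_interaction
  # the deficit shows up in the stepping/step1 intercept
  icpt <- fit$fixed$estimate[fit$fixed$term == "(Intercept)"]
  expect_lt(icpt, 0)
  expect_lt(abs(icpt + 7.3), 6)   # within sampling noise at n = 12
  expect_gt(fit$icc, 0)
})
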