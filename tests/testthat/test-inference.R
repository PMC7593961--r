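# Inference: covariate transforms, censored robust mixed model, contrasts,
# Bayesian correlations.

test_that("covariate transforms and scalers round-trip", {
  raw <- data.frame(tcne = c(100, 10, 1000), music_years = c(8, 0, 27),
                    age = c(20, 45, 70))
  tab <- transform_covariates(raw)
  expect_equal(tab$log10_tcne, c(2, 1, 3))
  expect_equal(tab$mus, c(2, 0, 3))
  sc <- attr(tab, "scalers")
  expect_equal(invert_standardization(tab$age_std, sc, "age"), raw$age)
  expect_error(transform_covariates(data.frame(tcne = c(1, -2))), "positive")
  expect_error(transform_covariates(data.frame(music_years = -1)),
               "nonnegative")
})

test_that("percent change per decade maps log slopes correctly", {
  expect_equal(percent_change_per_decade(0), 0)
  expect_equal(percent_change_per_decade(log(0.83) / 10), -17)
  b <- seq(-0.05, 0.05, by = 0.01)
  expect_true(all(diff(percent_change_per_decade(b)) > 0))
})

fake_fit <- function(draws_mat) {
  structure(list(draws = coda::mcmc.list(coda::mcmc(draws_mat)),
                 coef_names = colnames(draws_mat)),
            class = "censored_lmm_fit")
}

test_that("derived contrasts are computed drawwise on the log scale", {
  m <- cbind(hi = rep(-0.02, 100), lo = rep(-0.01, 100))
  fit <- fake_fit(m)
  ct <- derived_contrasts(fit, list(level_ratio = c("hi", "lo")),
                          transform = percent_change_per_decade)
  expect_equal(ct$median, percent_change_per_decade(-0.01), tolerance = 1e-9)
  # symmetric slopes centre the contrast on zero
  m2 <- cbind(a = rnorm(500, 0, 1e-3), b = rnorm(500, 0, 1e-3))
  ct2 <- derived_contrasts(fake_fit(m2), list(d = c("a", "b")))
  expect_lt(ct2$lower, 0); expect_gt(ct2$upper, 0)
  expect_error(coef_draws(fit, "nope"), "no coefficient")
})

test_that("censored fit recovers a known slope and beats complete cases", {
  st <- censored_recovery_study(n_replicates = 2, n_subjects = 80,
                                mcmc = list(n_chains = 2, n_adapt = 300,
                                            n_iter = 800),
                                seed = 42)
  expect_equal(st$coverage, 2)
  expect_equal(st$mean_censoring_rate, 0.3, tolerance = 0.12)
  expect_lt(st$bias_censored_pct, st$bias_complete_case_pct)
})

test_that("with no censored rows the censored spec matches the plain fit", {
  co <- sample_cohort(60, seed = 15)
  tr <- default_truth() # baseline 150 nV: nothing near the 0.38 nV floor
  tab <- transform_covariates(simulate_abr_measurement_table(co, tr, seed = 16))
  expect_false(any(tab$censored))
  fixed <- c("age_std", "sex")
  f1 <- fit_model(tab, model_spec("amplitude", fixed, censored = "censored",
                                  log_response = TRUE),
                  n_adapt = 300, n_iter = 800, seed = 9)
  f2 <- fit_model(tab, model_spec("amplitude", fixed, censored = NULL,
                                  log_response = TRUE),
                  n_adapt = 300, n_iter = 800, seed = 9)
  expect_identical(f1$summary$median, f2$summary$median) # same sampler path
})

test_that("a zero-effect simulation keeps the null inside the 99% CI", {
  co <- sample_cohort(60, seed = 21)
  tr <- default_truth()
  tr$abr$age_slope <- 0; tr$abr$sex_m <- 0; tr$abr$pta_slope <- 0
  tab <- transform_covariates(simulate_abr_measurement_table(co, tr, seed = 22))
  fit <- fit_model(tab, model_spec("amplitude", c("age_std", "sex"),
                                   censored = "censored", log_response = TRUE),
                   n_adapt = 300, n_iter = 800, seed = 10)
  s <- fit$summary[fit$summary$parameter %in% c("age_std", "sexM"), ]
  expect_true(all(s$lower < 0 & s$upper > 0))
})

test_that("the robust correlation posterior matches a known coefficient", {
  # construct a pair with an empirical correlation of exactly 0.84
  set.seed(31)
  n <- 102
  x <- scale(rnorm(n))[, 1]
  e <- stats::residuals(lm(rnorm(n) ~ x))
  y <- 0.84 * x + sqrt(1 - 0.84^2) * scale(e)[, 1]
  bc <- bayes_correlation_matrix(data.frame(x = x, y = y), seed = 5)
  expect_equal(bc$median, 0.84, tolerance = 0.05)
  expect_true(bc$lower < bc$median & bc$median < bc$upper)
})

test_that("independent columns cover zero; collinear columns warn", {
  set.seed(33)
  ind <- data.frame(a = rnorm(80), b = rnorm(80), c = rnorm(80))
  bc <- bayes_correlation_matrix(ind, seed = 6)
  expect_true(all(bc$lower < 0 & bc$upper > 0))
  col <- data.frame(a = rnorm(200))
  col$b <- 2 * col$a + 1
  expect_warning(bc2 <- bayes_correlation_matrix(col, seed = 7),
                 "degenerate")
  expect_gt(bc2$median, 0.99)
  expect_error(bayes_correlation_matrix(ind[1:2, ]), "at least 3")
})

test_that("posterior summaries respect ordering and chain pooling", {
  set.seed(40)
  d <- coda::mcmc.list(coda::mcmc(matrix(rnorm(2000), ncol = 2,
                                         dimnames = list(NULL, c("a", "b")))),
                       coda::mcmc(matrix(rnorm(2000), ncol = 2,
                                         dimnames = list(NULL, c("a", "b")))))
  s1 <- posterior_summary(d)
  s2 <- posterior_summary(coda::mcmc.list(d[[2]], d[[1]]))
  expect_equal(s1$median, s2$median)
  expect_true(all(s1$lower <= s1$median & s1$median <= s1$upper))
  expect_false(any(is.na(s1$rhat)))
})
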