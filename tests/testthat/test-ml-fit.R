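# reduced settings keep the optimisation fast while exercising the full path
fast_settings <- function(beta_grid = c(0.5, 1, 2), P_grid = c(0, 0.1, 0.3), ...)
  ml_settings(n_nodes = 1024, beta_grid = beta_grid, P_grid = P_grid,
              profile_points = 21, refine = FALSE,
              optim_control = list(maxit = 250, reltol = 1e-7), ...)

test_that("support intervals from a quadratic profile match the closed form", {
  s <- 0.4; th_hat <- 2
  theta <- seq(0, 4, length.out = 81)
  ll <- -(theta - th_hat)^2 / (2 * s^2)
  si <- support_interval(theta, ll, drop = 2)
  expect_equal(si$lower, th_hat - 2 * s, tolerance = 1e-3)
  expect_equal(si$upper, th_hat + 2 * s, tolerance = 1e-3)
  expect_false(si$open_lower || si$open_upper)
  expect_true(si$lower <= si$theta_hat && si$theta_hat <= si$upper)
})

test_that("monotone and flat profiles produce open interval ends", {
  theta <- seq(0, 1, length.out = 20)
  si <- support_interval(theta, 5 * theta, drop = 2)
  expect_true(si$open_upper)
  expect_false(si$open_lower)
  expect_warning(si_flat <- support_interval(theta, rep(1, 20)), "flat")
  expect_true(si_flat$open_lower && si_flat$open_upper)
})

test_that("a full fit recovers generating parameters on one dataset", {
  tab <- simulate_ma_experiment(
    ma_params(U = 0.002, G = 994, P = 0.1, beta = 1, alpha = 1 / 0.15,
              sigma_env = 0.03),
    ma_design(n_ma = 90, n_control = 0, ancestor_reps = c(liquid_growth = 16)),
    traits = "liquid_growth", seed = 42)
  lv <- line_values(tab, "liquid_growth")
  fit <- fit_ml(lv$ancestor, unname(lv$MA), G = 994,
                settings = fast_settings())
  expect_s3_class(fit, "ml_fit")
  expect_true(is.finite(fit$loglik))
  # point estimate within the support interval by construction
  expect_true(fit$support$U$lower <= fit$params_hat$U + 1e-12)
  expect_true(fit$params_hat$U <= fit$support$U$upper + 1e-12)
  # generating values inside the support intervals for this seed
  expect_true(fit$support$U$lower <= 0.002 && 0.002 <= fit$support$U$upper)
  expect_true(fit$support$Ea$lower <= 0.15 && 0.15 <= fit$support$Ea$upper)
  # grid evaluated all beta x P cells
  expect_gte(nrow(fit$profile), 9)
})

test_that("null data drives the mutation rate to the lower boundary", {
  set.seed(5)
  anc <- rnorm(16, 1, 0.03)
  lines <- rnorm(30, 1, 0.03)
  # the effect-size profile is flat when essentially no mutations are seen
  expect_warning(
    fit <- fit_ml(anc, lines, G = 994,
                  settings = fast_settings(P_grid = 0, beta_grid = 1)),
    "flat")
  expect_lt(fit$params_hat$M, 0.5)  # well under one expected mutation
  expect_true(fit$support$U$open_lower)  # interval reaches the U = 0 bound
})

test_that("equal-effects model nests the null and wins on its own data", {
  set.seed(6)
  tab <- simulate_ma_experiment(
    ma_params(U = 0.003, G = 994, P = 0, beta = 500, alpha = 500 / 0.12,
              sigma_env = 0.02),
    ma_design(n_ma = 60, n_control = 0, ancestor_reps = c(liquid_growth = 16)),
    traits = "liquid_growth", seed = 61)
  lv <- line_values(tab, "liquid_growth")
  s <- fast_settings(P_grid = c(0, 0.1))
  fit_ee <- fit_equal_effects(lv$ancestor, unname(lv$MA), G = 994, settings = s)
  fit_g <- fit_ml(lv$ancestor, unname(lv$MA), G = 994,
                  settings = fast_settings(P_grid = c(0, 0.1),
                                           beta_grid = c(1, 4)))
  expect_true(fit_ee$equal_effects)
  # the equal-effects likelihood is at least competitive on equal-effects data
  expect_gte(fit_ee$loglik, fit_g$loglik - 2)
  expect_equal(fit_ee$params_hat$U, 0.003, tolerance = 0.5)
  expect_equal(fit_ee$params_hat$E_a, 0.12, tolerance = 0.25)
})
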