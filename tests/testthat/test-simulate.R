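test_that("parameter validation rejects impossible models", {
  expect_error(ma_params(U = -1), "U must")
  expect_error(ma_params(U = 0.001, P = 1.5), "P must")
  expect_error(ma_params(U = 0.001, alpha = 0), "alpha")
  expect_error(ma_params(U = 0.001, sigma_env = NaN), "non-finite")
  p <- ma_params(U = 0.002, G = 994)
  expect_equal(p$M, 1.988)
})

test_that("null model (U = 0) gives pure assay noise around 1", {
  par <- ma_params(U = 0, sigma_env = 0.05)
  tab <- simulate_ma_experiment(par, ma_design(n_ma = 400, n_control = 0,
                                               ancestor_reps = c(liquid_growth = 10)),
                                traits = "liquid_growth", seed = 11)
  ma <- line_values(tab, "liquid_growth")$MA
  expect_equal(mean(ma), 1, tolerance = 0.01)
  expect_lt(abs(var(ma) - 0.05^2), 3 * 0.05^2 * sqrt(2 / 399))
  expect_true(all(attr(tab, "truth")$liquid_growth$ma_counts == 0))
})

test_that("compound-Poisson moment identities hold within Monte-Carlo error", {
  # E[shift] = M (2P-1) beta/alpha ; Var[shift] = M beta(beta+1)/alpha^2
  n <- 40000
  par <- ma_params(U = 0.002, G = 994, P = 0.1, beta = 1, alpha = 6.67,
                   sigma_env = 0.03)
  tab <- simulate_ma_experiment(par, ma_design(n_ma = n, n_control = 0,
                                               ancestor_reps = c(liquid_growth = 10)),
                                traits = "liquid_growth", seed = 5)
  shift <- attr(tab, "truth")$liquid_growth$ma_true - 1
  m_th <- par$M * (2 * par$P - 1) * par$beta / par$alpha
  v_th <- par$M * par$beta * (par$beta + 1) / par$alpha^2
  expect_equal(mean(shift), m_th, tolerance = 4 * sqrt(v_th / n) / abs(m_th))
  expect_equal(var(shift), v_th, tolerance = 0.05)
  # symmetric effects leave the mean at 1
  par2 <- ma_params(U = 0.003, P = 0.5, beta = 2, alpha = 10, sigma_env = 0.02)
  tab2 <- simulate_ma_experiment(par2, ma_design(n_ma = n, n_control = 0,
                                                 ancestor_reps = c(total_spores = 10)),
                                 traits = "total_spores", seed = 6)
  expect_equal(mean(attr(tab2, "truth")$total_spores$ma_true), 1,
               tolerance = 0.005)
})

test_that("same seed reproduces the table bit for bit", {
  par <- ma_params(U = 0.002, P = 0.2)
  d <- ma_design(n_ma = 20, n_control = 3)
  t1 <- simulate_ma_experiment(par, d, traits = c("liquid_growth", "spore_germination"),
                               seed = 99)
  t2 <- simulate_ma_experiment(par, d, traits = c("liquid_growth", "spore_germination"),
                               seed = 99)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "truth"), attr(t2, "truth"))
})

test_that("kappa = 0 controls are mutation-free and ancestor-like", {
  par <- ma_params(U = 0.005, P = 0, beta = 1, alpha = 8, sigma_env = 0.03)
  tab <- simulate_ma_experiment(par, ma_design(n_ma = 5, n_control = 40,
                                               ancestor_reps = c(liquid_growth = 40),
                                               control_retention = 0),
                                traits = "liquid_growth", seed = 21)
  expect_true(all(attr(tab, "truth")$liquid_growth$control_counts == 0))
  lv <- line_values(tab, "liquid_growth")
  wt <- wilcoxon_rank_sum(lv$ancestor, unname(lv$control))
  expect_gt(wt$p_value, 0.05)
})

test_that("germination counts follow binomial moments and bounds", {
  expect_error(simulate_germination_counts(1.2), "\\[0, 1\\]")
  expect_equal(simulate_germination_counts(1, plates = 3, spores_per_plate = 50),
               c(50, 50, 50))
  expect_equal(simulate_germination_counts(0, plates = 2), c(0, 0))
  set.seed(8)
  draws <- replicate(4000, sum(simulate_germination_counts(0.5, 2, 100)))
  expect_equal(mean(draws), 100, tolerance = 0.01)
  expect_equal(sd(draws), sqrt(200 * 0.25), tolerance = 0.1)
})

test_that("germination trait is emitted as proportions in [0, 1]", {
  par <- ma_params(U = 0.003, P = 0, beta = 1, alpha = 4, sigma_env = 0.01)
  tab <- simulate_ma_experiment(par, ma_design(n_ma = 50, n_control = 0,
                                               ancestor_reps = c(spore_germination = 17)),
                                traits = "spore_germination", seed = 3)
  v <- tab$value[tab$trait == "spore_germination"]
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(abs(v * 100 - round(v * 100)) < 1e-12))  # counts over 100 spores
})

test_that("competition counts respect neutrality and odds arithmetic", {
  expect_error(simulate_competition_counts(0), "true_index")
  set.seed(4)
  # neutral line: labelled spore fraction tracks labelled cell fraction
  asy <- do.call(rbind, replicate(400, simulate_competition_counts(1), simplify = FALSE))
  expect_equal(mean(asy$n_spores_labeled / asy$n_spores_total),
               mean(asy$n_cells_labeled / asy$n_cells_total), tolerance = 0.01)
  # index 1.5 at an equal mix puts the line's spore share near 0.6
  asy2 <- do.call(rbind, replicate(400, simulate_competition_counts(1.5), simplify = FALSE))
  line_lab <- asy2[asy2$labeled_strain == "line", ]
  expect_equal(mean(line_lab$n_spores_labeled / line_lab$n_spores_total),
               1.5 / 2.5, tolerance = 0.015)
})
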