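test_that("analytic N/C trajectory matches its closed form and limits", {
  expect_equal(nc_trajectory_analytic(0.10, 0.075, 0.006, 0), 0.10)
  expect_equal(nc_trajectory_analytic(0.10, 0.075, 0.006, 1e6), 0.075)
  expect_equal(nc_trajectory_analytic(0.10, 0.075, 0.006, 60),
               0.075 + 0.025 * exp(-0.36), tolerance = 1e-12)
  # deviation halves after one doubling time ln2 / gammaC
  t_half <- log(2) / 0.006
  expect_equal(nc_trajectory_analytic(0.10, 0.075, 0.006, t_half), 0.0875,
               tolerance = 1e-10)
})

test_that("simulated exponential growth follows the analytic N/C solution", {
  t_grid <- seq(0, 200, by = 4)
  tr <- simulate_growth(100, 10, 0.006, 0.075, t_grid)
  expect_equal(tr$nc, nc_trajectory_analytic(0.10, 0.075, 0.006, t_grid),
               tolerance = 1e-10)
  # fixed point: nc0 = f0 stays put in both modes
  for (mode in c("exponential", "linear")) {
    trf <- simulate_growth(100, 7.5, 0.006, 0.075, t_grid, mode = mode)
    expect_equal(trf$nc, rep(0.075, length(t_grid)), tolerance = 1e-12)
  }
  expect_error(simulate_growth(100, 10, -0.1, 0.075), "gammaC")
  expect_error(simulate_growth(100, 110, 0.006, 0.075), "VN0 < VC0")
})

test_that("numerical ODE integration agrees with the closed forms over 10 generations", {
  t_grid <- seq(0, 10 * log(2) / 0.006, length.out = 21)
  num <- integrate_growth_numeric(100, 10, 0.006, 0.075, t_grid, dt = 0.5)
  ana <- simulate_growth(100, 10, 0.006, 0.075, t_grid)
  expect_equal(num$vc_um3, ana$vc_um3, tolerance = 1e-8)
  expect_equal(num$vn_um3, ana$vn_um3, tolerance = 1e-8)
  expect_equal(num$nc, ana$nc, tolerance = 1e-8)
})

test_that("N/C converges to f0 monotonically with no overshoot from any start", {
  t_grid <- seq(0, 2000, by = 20)
  for (nc0 in c(0.01, 0.05, 0.075, 0.2, 0.9)) {
    nc <- nc_trajectory_analytic(nc0, 0.075, 0.006, t_grid)
    dev <- abs(nc - 0.075)
    expect_true(all(diff(dev) <= 1e-15))
    expect_true(all(sign(nc - 0.075) == sign(nc0 - 0.075)) || nc0 == 0.075)
  }
})

test_that("linear growth corrects N/C deviations more slowly than exponential", {
  t_dbl <- log(2) / 0.006
  exp_tr <- simulate_growth(300, 45, 0.006, 0.075, c(0, t_dbl),
                            mode = "exponential")
  lin_tr <- simulate_growth(300, 45, 0.006, 0.075, c(0, t_dbl),
                            mode = "linear")
  expect_lt(abs(exp_tr$nc[2] - 0.075), abs(lin_tr$nc[2] - 0.075))
})

test_that("growth-rate regression recovers gammaC and its initial-x bias form", {
  g <- 0.006
  t_grid <- seq(0, 40, by = 4)
  cohort <- do.call(rbind, lapply(1:40, function(i) {
    simulate_growth(50 + 5 * i, (50 + 5 * i) * 0.075, g, 0.075, t_grid,
                    cell_id = i)
  }))
  fit_mean <- suppressWarnings(fit_growth_rate(cohort, x = "mean"))
  expect_equal(fit_mean$gammaC, g, tolerance = 0.01)
  fit_init <- suppressWarnings(fit_growth_rate(cohort, x = "initial"))
  # OLS volume slope on an exponential is V0 * cov(t, e^(gt)) / var(t),
  # so the initial-x regression inflates gammaC by that known factor
  bias <- cov(t_grid, exp(g * t_grid)) / var(t_grid) / g
  expect_equal(fit_init$gammaC, g * bias, tolerance = 1e-6)
  expect_gt(fit_init$gammaC / g, 1.05)
  # size-independent (same dV/dt for all sizes) growth gives gammaC ~ 0
  flat <- do.call(rbind, lapply(1:40, function(i) {
    v0 <- 50 + 5 * i
    simulate_growth(v0, v0 * 0.075, 0.6 / v0, 0.075, t_grid,
                    mode = "linear", cell_id = i)
  }))
  expect_lt(abs(suppressWarnings(fit_growth_rate(flat))$gammaC), 1e-10)
  # noisy recovery within 2 SE
  pop <- gen_homeostasis_population(seed = 77, n_cells = 300)
  noisy <- fit_growth_rate(pop)
  expect_lt(abs(noisy$gammaC - g), 2 * noisy$stderr)
})

test_that("homeostasis regression recovers the correction rate and f0", {
  pop <- gen_homeostasis_population(seed = 5, n_cells = 1000)
  h <- fit_correction_rate(pop, gammaC = 0.006, f0 = 0.075)
  expect_lt(abs(h$gammaNC + 0.006), 3 * h$stderr_gammaNC)
  expect_lt(abs(h$f0_hat - 0.075), 3 * h$stderr_f0)
  expect_equal(h$predicted_line$slope, -0.006)
  # noiseless cohort: mean-x estimator is unbiased to the grid level
  pop0 <- gen_homeostasis_population(seed = 6, n_cells = 200, noise_cv = 0)
  h0 <- fit_correction_rate(pop0)
  expect_equal(h0$gammaNC, -0.006, tolerance = 0.005)
  expect_equal(h0$f0_hat, 0.075, tolerance = 1e-6)
  # degenerate spread is rejected
  flat <- do.call(rbind, lapply(1:20, function(i)
    simulate_growth(100 + i, (100 + i) * 0.075, 0.006, 0.075,
                    cell_id = i)))
  expect_error(fit_correction_rate(flat), "spread")
})

test_that("estimators are consistent: error shrinks with cohort size and noise", {
  h_small <- fit_correction_rate(
    gen_homeostasis_population(seed = 8, n_cells = 100, noise_cv = 0.05))
  h_large <- fit_correction_rate(
    gen_homeostasis_population(seed = 8, n_cells = 2000, noise_cv = 0.01))
  expect_lt(abs(h_large$gammaNC + 0.006), abs(h_small$gammaNC + 0.006) + 1e-4)
  expect_lt(h_large$stderr_gammaNC, h_small$stderr_gammaNC)
  expect_lt(abs(h_large$gammaNC + 0.006) / 0.006, 0.05)
  expect_lt(abs(h_large$f0_hat - 0.075), 0.002)
})

test_that("mitotic timepoints are excluded and sparse cells dropped", {
  t_grid <- seq(0, 40, by = 4)
  cohort <- do.call(rbind, lapply(1:15, function(i)
    simulate_growth(60 + 10 * i, (60 + 10 * i) * 0.09, 0.006, 0.075, t_grid,
                    cell_id = i)))
  # corrupt some rows but mark them mitotic: estimates must be unaffected
  poisoned <- cohort
  sel <- poisoned$t_min == 20
  poisoned$vc_um3[sel] <- poisoned$vc_um3[sel] * 10
  poisoned$mitotic[sel] <- TRUE
  poisoned$nc <- poisoned$vn_um3 / poisoned$vc_um3
  clean <- cohort[cohort$t_min != 20, ]
  expect_equal(suppressWarnings(fit_growth_rate(poisoned))$gammaC,
               suppressWarnings(fit_growth_rate(clean))$gammaC,
               tolerance = 1e-12)
  # a cell reduced to 2 timepoints is dropped with a warning
  chopped <- rbind(clean[clean$cell_id != 1, ],
                   clean[clean$cell_id == 1, ][1:2, ])
  set.seed(3)
  chopped$vc_um3 <- chopped$vc_um3 * exp(rnorm(nrow(chopped), 0, 1e-4))
  expect_warning(fit_growth_rate(chopped), "dropped")
})

test_that("time to correct a deviation follows the log2 closed form", {
  res <- generations_to_correct(0.12, 0.075, 0.006, tolerance = 0.045 / 4)
  expect_equal(res$generations, 2, tolerance = 1e-12)
  res2 <- generations_to_correct(0.12, 0.075, 0.006, tolerance = 0.005)
  expect_equal(res2$generations, log2(9), tolerance = 1e-12)
  expect_equal(res2$time_min, log(9) / 0.006, tolerance = 1e-10)
  expect_gt(res2$generations, 3)  # multiple generations for a large shift
  expect_equal(generations_to_correct(0.08, 0.075, 0.006, 0.01)$generations, 0)
  expect_error(generations_to_correct(0.12, 0.075, 0.006, 0), "tolerance")
})
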