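test_that("shift normalization is the (C_iso/C_out, V/V_iso) map", {
  rec <- data.frame(cell_id = 1:3, compartment = "cell",
                    c_iso = 0.4, c_out = c(0.8, 0.4, 0.2),
                    v_iso_um3 = 100, v_um3 = c(62.5, 100, 175))
  pts <- normalize_shift_data(rec)
  expect_equal(pts$x, c(0.5, 1, 2))
  expect_equal(pts$y, c(0.625, 1, 1.75))
  expect_error(normalize_shift_data(rec[, -3]), "c_iso")
  rec$conc_units <- c("M-sorbitol", "M-sorbitol", "mOsm")
  expect_error(normalize_shift_data(rec), "mixed")
})

test_that("BVH fit recovers an exact line and honors the through-(1,1) constraint", {
  x <- c(0.4, 0.67, 1, 1.33, 2)
  pts <- data.frame(x = x, y = 0.75 * x + 0.25)
  fit <- suppressWarnings(fit_bvh_linear(pts))
  expect_equal(fit$slope, 0.75, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.25, tolerance = 1e-12)
  pts0 <- data.frame(x = x, y = x)
  fit0 <- suppressWarnings(fit_bvh_linear(pts0))
  expect_equal(fit0$slope, 1, tolerance = 1e-12)
  expect_equal(fit0$intercept, 0, tolerance = 1e-12)
  fitc <- suppressWarnings(fit_bvh_linear(pts, through_iso = TRUE))
  expect_equal(fitc$slope + fitc$intercept, 1)
  expect_equal(fitc$slope, 0.75, tolerance = 1e-12)
  expect_error(fit_bvh_linear(data.frame(x = c(1, 1, 1), y = 1:3)),
               "degenerate")
})

test_that("fitted BVH line passes through (1,1) within error on ideal-osmometer data", {
  for (seed in c(5, 17)) {
    sh <- gen_shift_dataset(seed = seed, n_cells = 300)
    fit <- fit_bvh_linear(normalize_shift_data(sh))
    se_sum <- sqrt(fit$stderr_slope^2 + fit$stderr_intercept^2)
    expect_lt(abs(fit$slope + fit$intercept - 1), 3 * se_sum)
    # intercept recovers the generating nu_b within 2 SE
    expect_lt(abs(fit$intercept - 0.25), 2 * fit$stderr_intercept)
  }
})

test_that("ideality test keeps nominal size on linear data and detects tension", {
  # type-I calibration: rejection rate near alpha over many null datasets
  set.seed(1234)
  n_rep <- 600
  alpha <- 0.05
  x_levels <- c(0.4, 0.67, 1, 1.33, 2)
  rejected <- 0L
  for (i in seq_len(n_rep)) {
    x <- rep(x_levels, each = 20)
    y <- 0.75 * x + 0.25 + rnorm(length(x), 0, 0.05)
    p <- ideality_test(data.frame(x = x, y = y))$p_value
    if (p < alpha) rejected <- rejected + 1L
  }
  rate <- rejected / n_rep
  expect_gte(rate, alpha / 2)
  expect_lte(rate, 2 * alpha)
  # power: a tension-curved forward model is rejected at n = 400
  # walled-cell scale effective tension (turgor-dominated, ~0.5 N/m)
  curve <- predict_bvh_curve(N = 37500, b = 25, sigma = 0.5, c_iso = 500,
                             cout_grid = rep(c(250, 400, 500, 700, 1000),
                                             each = 80))
  set.seed(7)
  y <- curve$y * exp(rnorm(nrow(curve), 0, 0.02))
  expect_lt(ideality_test(data.frame(x = curve$x, y = y))$p_value, 0.01)
  # minimal replicated two-level design still runs
  two <- data.frame(x = rep(c(0.5, 2), each = 3),
                    y = rep(c(0.6, 1.7), each = 3) + c(-0.01, 0, 0.01))
  res <- ideality_test(two)
  expect_true(is.finite(res$p_value) || res$p_value == 1)
  expect_error(ideality_test(data.frame(x = c(1, 2), y = c(1, 2))),
               "replication|levels")
})

test_that("theoretical BVH curve is linear without tension and flattened with it", {
  grid <- seq(100, 2000, by = 100)
  cv <- predict_bvh_curve(N = 37500, b = 25, sigma = 0, c_iso = 500,
                          cout_grid = grid)
  # exactly y = 0.75 x + 0.25 (nu_b = 25/100)
  expect_equal(cv$y, 0.75 * cv$x + 0.25, tolerance = 1e-10)
  tense <- predict_bvh_curve(N = 37500, b = 25, sigma = 0.05, c_iso = 500,
                             cout_grid = grid)
  hypo <- tense$x > 1
  expect_true(all(tense$y[hypo] < cv$y[hypo]))
  # sigma -> 0 converges pointwise to the linear law
  near0 <- predict_bvh_curve(N = 37500, b = 25, sigma = 1e-8, c_iso = 500,
                             cout_grid = grid)
  expect_equal(near0$y, cv$y, tolerance = 1e-5)
})

test_that("chondrocyte-scale parameters produce a saturating hypotonic branch", {
  # 1 mOsm um^3 = 1 mol/m^3 x 1e-18 m^3 = 1e-18 mol
  N <- 4e-16 / 1e-18
  cv <- predict_bvh_curve(N = N, b = 5, sigma = 0.02, c_iso = 400,
                          cout_grid = 400 / seq(1, 8, by = 0.5))
  # swelling saturates: incremental volume gain shrinks as x grows
  gains <- diff(cv$y) / diff(cv$x)
  expect_true(all(diff(gains) < 1e-9))
})

test_that("osmolyte inference inverts the ideal forward model exactly", {
  est <- infer_osmolytes(100, 62.5, +500, 25)
  expect_equal(est$C_iso_internal, 500, tolerance = 1e-12)
  expect_equal(est$N, 37500, tolerance = 1e-12)
  # round trip on forward-generated shifts, any magnitude
  b <- 25; N <- 37500; C1 <- 500
  for (dC in c(-200, -100, 200, 400, 600)) {
    V2 <- b + N / (C1 + dC)
    est <- infer_osmolytes(100, V2, dC, b)
    expect_equal(est$N, N, tolerance = 1e-10)
    expect_equal(est$C_iso_internal, C1, tolerance = 1e-10)
  }
  # population with N proportional to V_iso: inferred N linear through b
  v_iso <- c(60, 80, 100, 140, 180)
  conc <- 500
  Ns <- conc * (v_iso - 0.25 * v_iso)
  est_n <- vapply(seq_along(v_iso), function(i) {
    V2 <- 0.25 * v_iso[i] + Ns[i] / (conc + 300)
    infer_osmolytes(v_iso[i], V2, 300, 0.25 * v_iso[i])$N
  }, numeric(1))
  fit <- lm(est_n ~ v_iso)
  expect_equal(unname(coef(fit)[1]), 0, tolerance = 1e-6)
  expect_warning(infer_osmolytes(100, 110, +500, 25), "flagged")
  expect_error(infer_osmolytes(100, 20, +500, 25), "free volume")
})

test_that("unit conversions match their closed forms", {
  expect_equal(osmolarity_from_density(30e7), 498.2, tolerance = 1e-3)
  expect_lt(abs(osmolarity_from_density(30e7) - 500), 45)
  expect_equal(osmolarity_from_density(6.02214076e5), 1)
  expect_identical(osmolarity_from_density(0), 0)
  expect_error(osmolarity_from_density(-1), "non-negative")
  expect_equal(sphere_area_ratio(1), 1)
  expect_equal(sphere_area_ratio(1.40), 1.2514, tolerance = 1e-4)
  expect_equal(sphere_area_ratio(8), 4)
})
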