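test_that("MSD matches closed forms for ballistic and stationary toy tracks", {
  n <- 60
  ballistic <- data.frame(track_id = 1L, frame = 0:(n - 1),
                          x_um = 0.05 * (0:(n - 1)), y_um = 0)
  msd <- compute_msd(ballistic, dt = 0.01, max_lag_frames = 20)
  k <- 1:20
  expect_equal(msd$msd, (k * 0.05)^2, tolerance = 1e-12)
  expect_true(all(diff(msd$n_displacements) <= 0))
  # ballistic motion has alpha = 2
  expect_equal(suppressWarnings(fit_alpha(msd, 2:20))$alpha, 2,
               tolerance = 1e-10)
  still <- data.frame(track_id = 1L, frame = 0:(n - 1), x_um = 0, y_um = 0)
  expect_equal(compute_msd(still, max_lag_frames = 10)$msd, rep(0, 10))
  expect_error(compute_msd(still[1:3, ], max_lag_frames = 5), "minimum length")
})

test_that("frame gaps split tracks and short segments are dropped", {
  tr <- data.frame(track_id = 1L, frame = c(0:14, 30:44),
                   x_um = rnorm(30), y_um = rnorm(30))
  msd <- compute_msd(tr, max_lag_frames = 14)
  expect_equal(msd$n_tracks, 2L)  # two 15-frame segments
  expect_equal(max(msd$tau), 14 * 0.01)
})

test_that("truncated-MSD fit returns the exact D on a perfect line", {
  mk_line <- function(d) {
    structure(list(tau = (1:20) * 0.01, msd = 4 * d * (1:20) * 0.01,
                   n_displacements = rep(100L, 20), mode = "ensemble",
                   n_tracks = 10L, dt = 0.01), class = "msd_curve")
  }
  expect_equal(suppressWarnings(fit_deff(mk_line(0.55)))$D_eff, 0.55,
               tolerance = 1e-12)
  expect_equal(suppressWarnings(fit_deff(mk_line(0.40)))$D_eff, 0.40,
               tolerance = 1e-12)
  expect_error(fit_deff(mk_line(0.4), n_points = 50), "available")
})

test_that("Brownian calibration: D_eff and alpha recovered across seeds", {
  d_hat <- numeric(8)
  a_hat <- numeric(8)
  for (s in 1:8) {
    tr <- gen_brownian_tracks(seed = 100 + s, D = 0.40, duration = 3,
                              n_tracks = 60, loc_sd = 0)
    msd <- compute_msd(tr, max_lag_frames = 50)
    d_hat[s] <- fit_deff(msd)$D_eff
    a_hat[s] <- fit_alpha(msd)$alpha
  }
  expect_lt(abs(mean(d_hat) - 0.40) / 0.40, 0.02)
  expect_lt(abs(mean(a_hat) - 1), 0.05)
})

test_that("fBm calibration recovers alpha = 2H across Hurst values", {
  for (H in c(0.35, 0.4, 0.45, 0.5)) {
    tr <- gen_fbm_tracks(seed = round(1000 * H), D_scale = 0.5,
                         alpha = 2 * H, duration = 5, n_tracks = 80,
                         loc_sd = 0)
    a <- fit_alpha(compute_msd(tr, max_lag_frames = 50))$alpha
    expect_lt(abs(a - 2 * H), 0.05)
  }
})

test_that("static localization error offsets the MSD by 4 sigma^2 in expectation", {
  sig <- 0.03
  tr <- gen_brownian_tracks(seed = 21, D = 0.40, duration = 3,
                            n_tracks = 120, loc_sd = 0)
  noisy <- tr
  set.seed(22)
  noisy$x_um <- noisy$x_um + rnorm(nrow(noisy), 0, sig)
  noisy$y_um <- noisy$y_um + rnorm(nrow(noisy), 0, sig)
  m0 <- compute_msd(tr, max_lag_frames = 10)
  m1 <- compute_msd(noisy, max_lag_frames = 10)
  offset <- mean(m1$msd - m0$msd)
  expect_equal(offset, 4 * sig^2, tolerance = 0.1)
  # and the free-offset fit mode sees it as an intercept
  fit <- fit_deff(m1, offset = TRUE)
  expect_equal(fit$offset, 4 * sig^2, tolerance = 0.25)
})

test_that("Stokes-Einstein reference diffusivities match hand computations", {
  expect_equal(stokes_einstein_d0(20e-9, 303.15, 7.97e-4), 13.9,
               tolerance = 3e-3)
  expect_equal(stokes_einstein_d0(40e-9), stokes_einstein_d0(20e-9) / 2,
               tolerance = 1e-12)
  expect_equal(stokes_einstein_d0(20e-9, 298.15, 8.9e-4), 12.3,
               tolerance = 2e-2)
})

test_that("Phillies fits recover generating parameters", {
  conc <- seq(0.2, 1.6, by = 0.2)
  exact <- data.frame(conc = conc, deff = 13.9 * exp(-2 * conc))
  free <- fit_phillies(exact, "free")
  expect_equal(free$D0, 13.9, tolerance = 1e-6)
  expect_equal(free$beta, 2, tolerance = 1e-6)
  expect_equal(free$lam, 1, tolerance = 1e-6)
  fixed <- suppressWarnings(fit_phillies(exact, "fixed", lambda = 1))
  expect_equal(fixed$D0, 13.9, tolerance = 1e-10)
  expect_equal(fixed$beta, 2, tolerance = 1e-10)
  # the fixed-lambda path equals the closed-form linear regression
  X <- cbind(1, conc)
  co <- solve(crossprod(X), crossprod(X, log(exact$deff)))
  expect_equal(log(fixed$D0), co[1], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(-fixed$beta, co[2], tolerance = 1e-12, ignore_attr = TRUE)
  # noisy free-lambda fit covers the generating lambda = 1
  noisy <- gen_phillies_dataset(seed = 9)
  nf <- fit_phillies(noisy, "free")
  expect_lt(abs(nf$lam - 1), 2 * nf$se[["lam"]])
  expect_error(fit_phillies(exact[1:2, ], "fixed"), "distinct")
})

test_that("volume-parameterized Phillies fit matches the concentration form", {
  b <- 25; N_molar <- 37.5  # amount in M-equivalent x um^3 units
  vols <- seq(60, 180, by = 20)
  conc_equiv <- N_molar / (vols - b)  # ideal osmometer: C = N/(V - b)
  A <- 14; kappa <- 2 * N_molar  # A exp(-kappa/(V-b)) = A exp(-2 C) at beta = 2
  dat <- data.frame(volume = vols, deff = A * exp(-kappa / (vols - b)))
  fit <- suppressWarnings(phillies_vs_volume(dat, b))
  expect_equal(fit$A, A, tolerance = 1e-8)
  expect_equal(fit$kappa, kappa, tolerance = 1e-6)
  # monotone increasing D with V on the fitted curve
  pred <- fit$A * exp(-fit$kappa / (vols - b))
  expect_true(all(diff(pred) > 0))
  # consistency with fit_phillies on the equivalent concentrations
  cfit <- suppressWarnings(
    fit_phillies(data.frame(conc = conc_equiv, deff = dat$deff),
                 "fixed", lambda = 1))
  expect_equal(cfit$D0 * exp(-cfit$beta * conc_equiv), pred, tolerance = 1e-6)
  expect_error(phillies_vs_volume(data.frame(volume = 20, deff = 1), b),
               "exceed")
})

test_that("dilution inference inverts the lambda = 1 Phillies law", {
  fit <- structure(list(D0 = 13.9, beta = 2, lam = 1, lambda_fixed = TRUE),
                   class = "phillies_fit")
  expect_equal(infer_dilution_from_deff(1, fit, C_ref = 0.5), 0)
  d_ratio <- exp(2 * 0.5 * 0.11)
  expect_equal(infer_dilution_from_deff(d_ratio, fit, C_ref = 0.5), 0.11,
               tolerance = 1e-12)
  # Monte-Carlo round trip through a fitted model
  noisy <- gen_phillies_dataset(seed = 31, beta = 2, noise_cv = 0.05)
  nf <- fit_phillies(noisy, "fixed", lambda = 1)
  true_dil <- 0.08
  d_ratio <- exp(2 * 0.8 * true_dil)  # forward map at C_ref = 0.8, beta = 2
  est <- infer_dilution_from_deff(d_ratio, nf, C_ref = 0.8)
  expect_equal(est, true_dil, tolerance = 0.1)
  bad <- structure(list(beta = 0, lam = 1), class = "phillies_fit")
  expect_error(infer_dilution_from_deff(2, bad, 0.5), "beta")
})
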