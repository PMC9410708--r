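#' Mean square displacement of particle tracks
#'
#' Computes the time-averaged MSD of each track over all start points, then
#' a count-weighted ensemble mean across tracks.  Tracks are tables of 2-D
#' positions of 40-nm GEM nanoparticles sampled at a fixed frame interval
#' (100 Hz for 10 s in the reference protocol); frame gaps split a track
#' into segments before averaging.
#'
#' @param tracks data.frame with columns `track_id`, `frame`, `x_um`,
#'   `y_um` (optionally `t_s`).
#' @param dt frame interval in seconds (default 0.01).
#' @param max_lag_frames largest lag, in frames (default 100).
#' @param min_track_length minimum frames per (gap-split) segment
#'   (default 10).
#' @param mode `"ensemble"` (count-weighted mean of time-averaged per-track
#'   MSDs, the default) or `"per_track"` (returns the per-track matrix too).
#' @return an object of class `msd_curve`: data.frame fields `tau` (s),
#'   `msd` (um^2), `n_displacements`; attributes record the mode and number
#'   of tracks.  `"per_track"` adds a `per_track` matrix (tracks x lags).
#' @export
compute_msd <- function(tracks, dt = 0.01, max_lag_frames = 100,
                        min_track_length = 10,
                        mode = c("ensemble", "per_track")) {
  mode <- match.arg(mode)
  need <- c("track_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(tracks))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  segs <- .split_track_segments(tracks, min_track_length)
  if (length(segs) == 0)
    stop("no track reaches the minimum length of ", min_track_length,
         " frames", call. = FALSE)
  n_lags <- max_lag_frames
  sums <- numeric(n_lags)
  counts <- numeric(n_lags)
  per_track <- if (mode == "per_track")
    matrix(NA_real_, nrow = length(segs), ncol = n_lags) else NULL
  for (s in seq_along(segs)) {
    seg <- segs[[s]]
    n <- nrow(seg)
    kmax <- min(n_lags, n - 1)
    for (k in seq_len(kmax)) {
      dx <- seg$x_um[(1 + k):n] - seg$x_um[1:(n - k)]
      dy <- seg$y_um[(1 + k):n] - seg$y_um[1:(n - k)]
      sq <- dx * dx + dy * dy
      m <- length(sq)
      if (mode == "per_track") per_track[s, k] <- mean(sq)
      sums[k] <- sums[k] + sum(sq)
      counts[k] <- counts[k] + m
    }
  }
  keep <- counts > 0
  out <- structure(
    list(tau = (seq_len(n_lags) * dt)[keep],
         msd = (sums / pmax(counts, 1))[keep],
         n_displacements = counts[keep],
         mode = mode, n_tracks = length(segs), dt = dt),
    class = "msd_curve"
  )
  if (mode == "per_track") out$per_track <- per_track[, keep, drop = FALSE]
  out
}

# split tracks at frame gaps, drop short segments
.split_track_segments <- function(tracks, min_len) {
  segs <- list()
  for (tr in split(tracks, tracks$track_id)) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (any(duplicated(tr$frame)))
      stop("duplicated frames within track ", tr$track_id[1], call. = FALSE)
    brk <- cumsum(c(0, diff(tr$frame) != 1))
    for (piece in split(tr, brk)) {
      if (nrow(piece) >= min_len) segs[[length(segs) + 1L]] <- piece
    }
  }
  segs
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: %d lags (tau %.3g-%.3g s), %d tracks, mode '%s'\n",
              length(x$tau), min(x$tau), max(x$tau), x$n_tracks, x$mode))
  invisible(x)
}

#' Effective diffusivity from the truncated MSD
#'
#' Fits the first `n_points` lags of the MSD curve to the 2-D Brownian law
#' MSD(tau) = 4 D_eff tau by least squares through the origin.  The short
#' truncation makes D_eff an effective short-time mobility even when the
#' motion is subdiffusive at longer lags.
#'
#' @param msd an `msd_curve`.
#' @param n_points number of initial lags to fit (default 10).
#' @param offset if `TRUE`, add a free intercept (useful for quantifying
#'   static localization error, which offsets the MSD by 4 sigma_loc^2).
#'   Default `FALSE`.
#' @return object of class `diffusion_fit` with `D_eff` (um^2/s),
#'   `stderr_D`, `offset` (um^2 or NA), `n_lags_used`, `n_tracks`.
#' @export
fit_deff <- function(msd, n_points = 10, offset = FALSE) {
  stopifnot(inherits(msd, "msd_curve"))
  if (length(msd$tau) < n_points)
    stop(sprintf("requested %d lags but only %d available", n_points,
                 length(msd$tau)), call. = FALSE)
  tau <- msd$tau[seq_len(n_points)]
  y <- msd$msd[seq_len(n_points)]
  fit <- if (offset) stats::lm(y ~ tau) else stats::lm(y ~ 0 + tau)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(
    list(D_eff = unname(co[["tau"]]) / 4,
         stderr_D = unname(se[["tau"]]) / 4,
         offset = if (offset) unname(co[["(Intercept)"]]) else NA_real_,
         alpha = NA_real_, stderr_alpha = NA_real_,
         n_lags_used = n_points, n_tracks = msd$n_tracks, model = fit),
    class = "diffusion_fit"
  )
}

#' Anomalous diffusion exponent from the MSD power law
#'
#' Fits log(MSD) against log(tau) over a lag range; the slope is the
#' anomalous exponent alpha of MSD ~ tau^alpha (alpha = 1 Brownian,
#' alpha < 1 subdiffusive).
#'
#' @param msd an `msd_curve`.
#' @param fit_range integer lag indices to use (default `2:50`).
#' @return object of class `diffusion_fit` with `alpha`, `stderr_alpha`
#'   populated (and the apparent `D_eff` = exp(intercept)/4 at tau = 1 s).
#' @export
fit_alpha <- function(msd, fit_range = 2:50) {
  stopifnot(inherits(msd, "msd_curve"))
  fit_range <- fit_range[fit_range <= length(msd$tau)]
  if (length(fit_range) < 5)
    stop("need at least 5 lags in the fit range", call. = FALSE)
  tau <- msd$tau[fit_range]
  y <- msd$msd[fit_range]
  pos <- y > 0
  if (!all(pos)) {
    warning(sum(!pos), " non-positive MSD values excluded from the log fit",
            call. = FALSE)
    tau <- tau[pos]; y <- y[pos]
  }
  fit <- stats::lm(log(y) ~ log(tau))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(
    list(D_eff = exp(unname(co[["(Intercept)"]])) / 4,
         stderr_D = NA_real_, offset = NA_real_,
         alpha = unname(co[["log(tau)"]]),
         stderr_alpha = unname(se[["log(tau)"]]),
         n_lags_used = length(tau), n_tracks = msd$n_tracks, model = fit),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  if (!is.na(x$alpha))
    cat(sprintf("Anomalous exponent fit: alpha = %.3f (SE %.3f), %d lags, %d tracks\n",
                x$alpha, x$stderr_alpha, x$n_lags_used, x$n_tracks))
  else
    cat(sprintf("Truncated-MSD fit: D_eff = %.4g um^2/s (SE %.2g), %d lags, %d tracks\n",
                x$D_eff, x$stderr_D, x$n_lags_used, x$n_tracks))
  invisible(x)
}

#' Stokes-Einstein diffusivity of a sphere
#'
#' Reference free-solution diffusivity D0 = kB T / (6 pi eta r), converted
#' to um^2/s.  Default viscosity is water at 30 C.
#'
#' @param radius_m particle radius in meters (20e-9 for a 40-nm GEM).
#' @param temperature absolute temperature (K).
#' @param viscosity_Pa_s dynamic viscosity (Pa s); default 7.97e-4.
#' @return D0 in um^2/s.
#' @examples
#' stokes_einstein_d0(20e-9)  # ~13.9 um^2/s for a 40-nm particle at 30 C
#' @export
stokes_einstein_d0 <- function(radius_m, temperature = .DEFAULT_TEMPERATURE,
                               viscosity_Pa_s = 7.97e-4) {
  stopifnot(radius_m > 0, temperature > 0, viscosity_Pa_s > 0)
  d_m2_s <- .K_BOLTZMANN * temperature / (6 * pi * viscosity_Pa_s * radius_m)
  d_m2_s * 1e12
}

#' Fit the Phillies stretched-exponential concentration model
#'
#' Tracer self-diffusion in a polymer solution follows
#' D_eff = D0 exp(-beta C^lambda).  With `lambda` fixed the model is linear
#' in log D; with `lambda` free a nonlinear fit is initialized from the
#' lambda = 1 linear solution.
#'
#' @param data data.frame with columns `conc` and `deff`.
#' @param lambda_mode `"fixed"` or `"free"`.
#' @param lambda the exponent when `lambda_mode = "fixed"` (default 1).
#' @return object of class `phillies_fit`: `D0`, `beta`, `lam`,
#'   `lambda_fixed`, standard errors `se` (named), covariance `vcov`, and
#'   the fitted model object.
#' @export
fit_phillies <- function(data, lambda_mode = c("fixed", "free"), lambda = 1) {
  lambda_mode <- match.arg(lambda_mode)
  conc <- data$conc
  deff <- data$deff
  ok <- deff > 0
  if (!all(ok)) {
    warning(sum(!ok), " non-positive D values excluded", call. = FALSE)
    conc <- conc[ok]; deff <- deff[ok]
  }
  n_conc <- length(unique(conc))
  if (n_conc < 3) stop("need >= 3 distinct concentrations", call. = FALSE)
  lin_for <- function(lam) stats::lm(log(deff) ~ I(conc^lam))
  if (lambda_mode == "fixed") {
    fit <- lin_for(lambda)
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    return(structure(
      list(D0 = exp(unname(co[1])), beta = -unname(co[2]), lam = lambda,
           lambda_fixed = TRUE,
           se = c(logD0 = unname(se[1]), beta = unname(se[2]), lam = NA),
           vcov = stats::vcov(fit), model = fit),
      class = "phillies_fit"))
  }
  if (n_conc < 4)
    stop("free-lambda fit needs >= 4 distinct concentrations", call. = FALSE)
  init <- lin_for(1)
  start <- list(logD0 = unname(stats::coef(init)[1]),
                beta = max(-unname(stats::coef(init)[2]), 1e-8), lam = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(log(deff) ~ logD0 - beta * conc^lam,
                      start = start,
                      lower = c(-Inf, 0, 1e-3), upper = c(Inf, Inf, 5),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("free-lambda fit did not converge (lambda = 1 linear fit: D0 = ",
           signif(exp(start$logD0), 4), ", beta = ", signif(start$beta, 4),
           "); ", conditionMessage(e), call. = FALSE))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(
    list(D0 = exp(unname(co["logD0"])), beta = unname(co["beta"]),
         lam = unname(co["lam"]), lambda_fixed = FALSE,
         se = c(logD0 = unname(se["logD0"]), beta = unname(se["beta"]),
                lam = unname(se["lam"])),
         vcov = stats::vcov(fit), model = fit),
    class = "phillies_fit")
}

#' @export
print.phillies_fit <- function(x, ...) {
  cat(sprintf("Phillies fit: D0 = %.4g um^2/s, beta = %.4g, lambda = %.3f%s\n",
              x$D0, x$beta, x$lam,
              if (x$lambda_fixed) " (fixed)" else
                sprintf(" (SE %.3f)", x$se[["lam"]])))
  invisible(x)
}

#' Phillies model against compartment volume
#'
#' For an ideal osmometer, internal macromolecule concentration scales as
#' 1/(V - b), so the lambda = 1 Phillies law becomes
#' D = A exp(-kappa / (V - b)).  Fitting log D against 1/(V - b) ties the
#' rheology directly to measured volumes with a single free scale.
#'
#' @param data data.frame with columns `volume` (um^3) and `deff`.
#' @param b non-osmotic volume (um^3); all volumes must exceed it.
#' @return object of class `phillies_volume_fit` with `A`, `kappa`, `b`,
#'   standard errors and the `lm` model.
#' @export
phillies_vs_volume <- function(data, b) {
  v <- data$volume
  deff <- data$deff
  if (any(v <= b))
    stop("all volumes must exceed the non-osmotic volume b", call. = FALSE)
  ok <- deff > 0
  if (!all(ok)) {
    warning(sum(!ok), " non-positive D values excluded", call. = FALSE)
    v <- v[ok]; deff <- deff[ok]
  }
  invfree <- 1 / (v - b)
  fit <- stats::lm(log(deff) ~ invfree)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(
    list(A = exp(unname(co[1])), kappa = -unname(co[2]), b = b,
         se = c(logA = unname(se[1]), kappa = unname(se[2])), model = fit),
    class = "phillies_volume_fit")
}

#' @export
print.phillies_volume_fit <- function(x, ...) {
  cat(sprintf(
    "Phillies-vs-volume fit: A = %.4g um^2/s, kappa = %.4g um^3, b = %g um^3\n",
    x$A, x$kappa, x$b))
  invisible(x)
}

#' Predict D_eff from a Phillies fit
#'
#' @param object a `phillies_fit`.
#' @param conc concentrations at which to predict.
#' @param ... unused.
#' @return predicted D_eff values.
#' @export
predict.phillies_fit <- function(object, conc, ...) {
  object$D0 * exp(-object$beta * conc^object$lam)
}

#' Infer a relative concentration change from a D_eff ratio
#'
#' Inverts the lambda = 1 Phillies law: a fold-change in effective
#' diffusivity D_ratio = D_after/D_before implies a fractional
#' concentration change of the crowding macromolecules,
#' dilution = ln(D_ratio) / (beta C_ref).  Positive values mean dilution
#' (faster diffusion).
#'
#' @param D_ratio ratio of effective diffusivities (> 0).
#' @param phillies a `phillies_fit` (its `beta` is used; `lam` must be 1).
#' @param C_ref reference concentration, same units as the fit.
#' @return signed fractional concentration change (positive = dilution).
#' @export
infer_dilution_from_deff <- function(D_ratio, phillies, C_ref) {
  stopifnot(D_ratio > 0, C_ref > 0)
  if (phillies$beta <= 0)
    stop("cannot invert: fitted beta is not positive", call. = FALSE)
  if (abs(phillies$lam - 1) > 1e-6)
    stop("inversion assumes lambda = 1 (fit has lambda = ",
         signif(phillies$lam, 3), ")", call. = FALSE)
  log(D_ratio) / (phillies$beta * C_ref)
}
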