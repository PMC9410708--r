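#' Simulate coupled cell and nuclear growth
#'
#' Volume growth is driven by biosynthesis scaling with cytoplasmic volume:
#' dVC/dt = gammaC VC (exponential mode), and a fixed fraction f0 of newly
#' made osmotically active material enters the nucleus, dVN/dt =
#' f0 gammaC VC.  The N/C ratio then relaxes to f0 at rate gammaC with no
#' feedback.  A linear mode (dVC/dt = k constant, k = gammaC VC0) is
#' provided for contrast: it corrects N/C deviations more slowly in large
#' cells.
#'
#' @param VC0 initial cell volume (um^3).
#' @param VN0 initial nuclear volume (um^3), < `VC0`.
#' @param gammaC exponential growth rate (min^-1, > 0).
#' @param f0 nuclear fraction of synthesis (0 < f0 < 1).
#' @param t_grid times in minutes (default 0 to 40 by 4).
#' @param mode `"exponential"` or `"linear"`.
#' @param cell_id identifier for the output table.
#' @return data.frame of class `growth_trajectory`: `cell_id`, `t_min`,
#'   `vc_um3`, `vn_um3`, `nc`, `mitotic` (all FALSE).
#' @export
simulate_growth <- function(VC0, VN0, gammaC, f0,
                            t_grid = seq(0, 40, by = 4),
                            mode = c("exponential", "linear"),
                            cell_id = 1L) {
  mode <- match.arg(mode)
  if (gammaC <= 0) stop("`gammaC` must be positive", call. = FALSE)
  if (f0 <= 0 || f0 >= 1) stop("`f0` must be in (0, 1)", call. = FALSE)
  if (VC0 <= 0 || VN0 <= 0 || VN0 >= VC0)
    stop("need 0 < VN0 < VC0", call. = FALSE)
  if (mode == "exponential") {
    vc <- VC0 * exp(gammaC * t_grid)
    vn <- VN0 + f0 * (vc - VC0)
  } else {
    k <- gammaC * VC0
    vc <- VC0 + k * t_grid
    vn <- VN0 + f0 * k * t_grid
  }
  structure(
    data.frame(cell_id = cell_id, t_min = t_grid, vc_um3 = vc,
               vn_um3 = vn, nc = vn / vc, mitotic = FALSE),
    class = c("growth_trajectory", "data.frame"))
}

#' Analytic N/C-ratio trajectory
#'
#' Under exponential growth with nuclear fraction f0, the N/C ratio obeys
#' d(nc)/dt = gammaC (f0 - nc), whose solution is
#' nc(t) = f0 + (nc0 - f0) exp(-gammaC t): monotone relaxation to f0 with
#' time constant 1/gammaC and no overshoot.
#'
#' @param nc0 initial N/C ratio.
#' @param f0 equilibrium N/C ratio.
#' @param gammaC growth rate (min^-1, > 0).
#' @param t time(s) in minutes.
#' @return nc value(s) at `t`.
#' @export
nc_trajectory_analytic <- function(nc0, f0, gammaC, t) {
  if (gammaC <= 0) stop("`gammaC` must be positive", call. = FALSE)
  f0 + (nc0 - f0) * exp(-gammaC * t)
}

#' Time and generations needed to correct an N/C deviation
#'
#' Relaxation is exponential, so shrinking an initial deviation
#' |nc0 - f0| to a target tolerance takes t* = ln(deviation/tolerance) /
#' gammaC, i.e. log2(deviation/tolerance) doubling times.  Correcting a
#' substantial deviation therefore spans multiple generations.
#'
#' @param nc0 initial N/C ratio.
#' @param f0 equilibrium N/C ratio.
#' @param gammaC growth rate (min^-1).
#' @param tolerance residual deviation considered corrected (> 0).
#' @return list with `time_min` and `generations` (both 0 when the
#'   deviation is already within tolerance).
#' @export
generations_to_correct <- function(nc0, f0, gammaC, tolerance) {
  if (tolerance <= 0) stop("`tolerance` must be positive", call. = FALSE)
  if (gammaC <= 0) stop("`gammaC` must be positive", call. = FALSE)
  dev <- abs(nc0 - f0)
  if (dev <= tolerance) return(list(time_min = 0, generations = 0))
  t_star <- log(dev / tolerance) / gammaC
  list(time_min = t_star, generations = log2(dev / tolerance))
}

# per-cell OLS slope and means over the non-mitotic window
.per_cell_rates <- function(trajectories, min_timepoints = 3) {
  cols <- c("cell_id", "t_min", "vc_um3", "vn_um3")
  miss <- setdiff(cols, names(trajectories))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"mitotic" %in% names(trajectories)) trajectories$mitotic <- FALSE
  if (!"nc" %in% names(trajectories))
    trajectories$nc <- trajectories$vn_um3 / trajectories$vc_um3
  dropped <- 0L
  rows <- lapply(split(trajectories, trajectories$cell_id), function(tr) {
    tr <- tr[!tr$mitotic, , drop = FALSE]
    tr <- tr[order(tr$t_min), , drop = FALSE]
    if (nrow(tr) < min_timepoints || length(unique(tr$t_min)) < 2) {
      dropped <<- dropped + 1L
      return(NULL)
    }
    dvdt <- unname(stats::coef(stats::lm(vc_um3 ~ t_min, data = tr))["t_min"])
    dncdt <- unname(stats::coef(stats::lm(nc ~ t_min, data = tr))["t_min"])
    data.frame(cell_id = tr$cell_id[1],
               v0 = tr$vc_um3[1], v_mean = mean(tr$vc_um3),
               nc0 = tr$nc[1], nc_mean = mean(tr$nc),
               dvdt = dvdt, dncdt = dncdt, n_t = nrow(tr))
  })
  if (dropped > 0)
    warning(dropped, " cell(s) dropped for having fewer than ",
            min_timepoints, " usable timepoints", call. = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) < 10)
    stop("need >= 10 usable cells", call. = FALSE)
  out
}

#' Population growth-rate estimate
#'
#' Each cell's volume growth rate dV/dt is the OLS slope of its volume
#' time series over the imaging window (mitotic timepoints excluded).
#' Under exponential growth dV/dt = gammaC V, so regressing the per-cell
#' rates on a per-cell volume summary estimates gammaC as the slope.  The
#' default regressor is the window-mean volume, for which the finite-window
#' secant rate satisfies dV/dt = gammaC <V> exactly in continuous time; the
#' `"initial"` regressor (the plotted convention) carries a known upward
#' finite-window factor of about (e^(gT) - 1)/(gT).
#'
#' @param trajectories trajectory table (see [simulate_growth()] /
#'   [gen_homeostasis_population()]).
#' @param x volume regressor: `"mean"` (default) or `"initial"`.
#' @param min_timepoints minimum non-mitotic timepoints per cell.
#' @return list with `gammaC`, `stderr`, `n_cells`, `x`, the per-cell
#'   `rates` table and the `lm` model.
#' @export
fit_growth_rate <- function(trajectories, x = c("mean", "initial"),
                            min_timepoints = 3) {
  x <- match.arg(x)
  rates <- .per_cell_rates(trajectories, min_timepoints)
  xv <- if (x == "mean") rates$v_mean else rates$v0
  fit <- stats::lm(rates$dvdt ~ xv)
  list(gammaC = unname(stats::coef(fit)["xv"]),
       stderr = sqrt(diag(stats::vcov(fit)))[["xv"]],
       n_cells = nrow(rates), x = x, rates = rates, model = fit)
}

#' N/C homeostasis regression
#'
#' Regresses each cell's N/C-ratio change rate d(nc)/dt (OLS slope over the
#' window) on its N/C ratio.  The model d(nc)/dt = gammaC (f0 - nc)
#' predicts a line of slope gammaNC = -gammaC crossing zero at nc = f0;
#' the fitted x-intercept is therefore an estimate of f0 requiring no other
#' input.  When `gammaC` and `f0` are supplied, the parameter-free
#' predicted line is attached for comparison with the fit.
#'
#' @param trajectories trajectory table.
#' @param x N/C regressor: `"mean"` (default, unbiased over a finite
#'   window) or `"initial"` (the plotted convention, biased low in
#'   magnitude by about (1 - e^(-gT))/(gT)).
#' @param gammaC,f0 optional known values for the zero-free-parameter
#'   predicted line.
#' @param min_timepoints minimum non-mitotic timepoints per cell.
#' @param min_nc_spread minimum SD of the nc regressor for the regression
#'   to be meaningful (default 0.005).
#' @return object of class `homeostasis_fit`: `gammaNC` (slope, min^-1),
#'   `stderr_gammaNC`, `f0_hat` (x-intercept), `stderr_f0`, `n_cells`,
#'   per-cell `rates`, the `lm` model, and (if given) `predicted_line`
#'   as `list(slope = -gammaC, intercept = gammaC * f0)`.
#' @export
fit_correction_rate <- function(trajectories, x = c("mean", "initial"),
                                gammaC = NULL, f0 = NULL,
                                min_timepoints = 3, min_nc_spread = 0.005) {
  x <- match.arg(x)
  rates <- .per_cell_rates(trajectories, min_timepoints)
  xv <- if (x == "mean") rates$nc_mean else rates$nc0
  if (stats::sd(xv) < min_nc_spread)
    stop(sprintf(
      "N/C spread too small for a homeostasis regression (SD = %.4g < %g)",
      stats::sd(xv), min_nc_spread), call. = FALSE)
  fit <- stats::lm(rates$dncdt ~ xv)
  co <- stats::coef(fit)
  V <- stats::vcov(fit)
  slope <- unname(co["xv"])
  inter <- unname(co["(Intercept)"])
  f0_hat <- -inter / slope
  # delta-method SE of the x-intercept
  g <- c(-1 / slope, inter / slope^2)
  se_f0 <- sqrt(drop(t(g) %*% V[c("(Intercept)", "xv"), c("(Intercept)", "xv")] %*% g))
  structure(
    list(gammaNC = slope, stderr_gammaNC = sqrt(diag(V))[["xv"]],
         f0_hat = f0_hat, stderr_f0 = se_f0,
         n_cells = nrow(rates), x = x, rates = rates, model = fit,
         predicted_line = if (!is.null(gammaC) && !is.null(f0))
           list(slope = -gammaC, intercept = gammaC * f0) else NULL),
    class = "homeostasis_fit")
}

#' @export
print.homeostasis_fit <- function(x, ...) {
  cat(sprintf("N/C homeostasis regression (n = %d cells, x = %s)\n",
              x$n_cells, x$x))
  cat(sprintf("  gammaNC = %.5f min^-1 (SE %.2g)\n",
              x$gammaNC, x$stderr_gammaNC))
  cat(sprintf("  f0_hat  = %.4f (SE %.2g)\n", x$f0_hat, x$stderr_f0))
  if (!is.null(x$predicted_line))
    cat(sprintf("  parameter-free prediction: slope %.5f, zero at %.4f\n",
                x$predicted_line$slope,
                -x$predicted_line$intercept / x$predicted_line$slope))
  invisible(x)
}

#' Explicit numerical integration of the growth system
#'
#' Fourth-order Runge-Kutta integration of dVC/dt = gammaC VC,
#' dVN/dt = f0 gammaC VC.  Exists to validate the closed forms used
#' everywhere else; not needed for analysis.
#'
#' @inheritParams simulate_growth
#' @param dt integration step (min).
#' @return data.frame `t_min`, `vc_um3`, `vn_um3`, `nc`.
#' @export
integrate_growth_numeric <- function(VC0, VN0, gammaC, f0, t_grid, dt = 0.01) {
  deriv <- function(s) c(gammaC * s[1], f0 * gammaC * s[1])
  out <- matrix(NA_real_, nrow = length(t_grid), ncol = 2)
  s <- c(VC0, VN0)
  t_now <- t_grid[1]
  out[1, ] <- s
  for (i in seq_along(t_grid)[-1]) {
    while (t_now < t_grid[i] - 1e-12) {
      h <- min(dt, t_grid[i] - t_now)
      k1 <- deriv(s)
      k2 <- deriv(s + h / 2 * k1)
      k3 <- deriv(s + h / 2 * k2)
      k4 <- deriv(s + h * k3)
      s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t_now <- t_now + h
    }
    out[i, ] <- s
  }
  data.frame(t_min = t_grid, vc_um3 = out[, 1], vn_um3 = out[, 2],
             nc = out[, 2] / out[, 1])
}
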