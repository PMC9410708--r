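#' Parameters of the nested-osmometer model
#'
#' The cell and its nucleus are modelled as two nested spherical osmometers.
#' Each compartment holds a fixed amount of osmotically active
#' macromolecules (too large to cross the nuclear envelope) plus a
#' non-osmotic (dry) volume, and its membrane may carry an effective surface
#' tension.  Volumes adjust so that the colloid osmotic pressure difference
#' across each membrane balances the Laplace pressure of that membrane.
#'
#' @param NN nuclear osmolyte amount (mOsm um^3).
#' @param NCy cytoplasmic osmolyte amount (mOsm um^3).
#' @param bN nuclear non-osmotic volume (um^3).
#' @param bC whole-cell non-osmotic volume (um^3); the cytoplasmic part is
#'   `bC - bN`.
#' @param sigmaC effective cell-surface tension (N/m).
#' @param sigmaN nuclear-envelope tension (N/m).
#' @param temperature absolute temperature (K); default 303.15 (30 C).
#' @return an object of class `model_params`.
#' @examples
#' p <- model_params(NN = 2812.5, NCy = 34687.5, bN = 1.875, bC = 25)
#' nc_ratio_closed_form(p)  # 0.075
#' @export
model_params <- function(NN, NCy, bN, bC,
                         sigmaC = 0, sigmaN = 0,
                         temperature = .DEFAULT_TEMPERATURE) {
  stopifnot(is.numeric(NN), is.numeric(NCy), is.numeric(bN), is.numeric(bC))
  if (NN <= 0 || NCy <= 0)
    stop("osmolyte amounts NN and NCy must be positive", call. = FALSE)
  if (bN < 0 || bN > bC)
    stop("non-osmotic volumes must satisfy 0 <= bN <= bC", call. = FALSE)
  if (sigmaC < 0 || sigmaN < 0)
    stop("membrane tensions must be non-negative", call. = FALSE)
  if (temperature <= 0)
    stop("temperature must be positive (K)", call. = FALSE)
  structure(
    list(NN = NN, NCy = NCy, bN = bN, bC = bC, bCy = bC - bN,
         sigmaC = sigmaC, sigmaN = sigmaN, temperature = temperature),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Nested-osmometer parameters\n")
  cat(sprintf("  osmolyte amounts : NN = %g, NCy = %g mOsm um^3 (nuclear fraction %.4f)\n",
              x$NN, x$NCy, x$NN / (x$NN + x$NCy)))
  cat(sprintf("  non-osmotic vol. : bN = %g, bC = %g um^3\n", x$bN, x$bC))
  cat(sprintf("  tensions         : sigmaC = %g, sigmaN = %g N/m\n",
              x$sigmaC, x$sigmaN))
  cat(sprintf("  temperature      : %g K\n", x$temperature))
  invisible(x)
}

#' External medium
#'
#' @param Cout external osmolyte concentration (mOsm, > 0).
#' @param label optional condition label.
#' @return an object of class `medium`.
#' @export
medium <- function(Cout, label = NULL) {
  if (!is.numeric(Cout) || length(Cout) != 1L || Cout <= 0)
    stop("`Cout` must be a single positive concentration (mOsm)", call. = FALSE)
  structure(list(Cout = Cout, label = label), class = "medium")
}

#' Laplace pressure expressed as a concentration jump
#'
#' A spherical membrane of tension sigma around a volume V sustains a
#' pressure jump 2 sigma / R with R = (3V / 4 pi)^(1/3).  Dividing by
#' R_gas x T converts the pressure to the equivalent osmolyte concentration
#' difference, in mOsm, that would balance it.
#'
#' @param sigma membrane tension (N/m, >= 0).
#' @param V compartment volume (um^3, > 0).
#' @param temperature absolute temperature (K).
#' @return concentration jump in mOsm; zero iff `sigma` is zero.
#' @examples
#' laplace_concentration_jump(0.02, 4 * pi / 3, 303.15)  # R = 1 um: ~15.9 mOsm
#' @export
laplace_concentration_jump <- function(sigma, V,
                                       temperature = .DEFAULT_TEMPERATURE) {
  if (any(sigma < 0)) stop("`sigma` must be non-negative", call. = FALSE)
  if (any(V <= 0)) stop("volume must be positive", call. = FALSE)
  r_m <- (3 * V / (4 * pi))^(1 / 3) * 1e-6  # um -> m
  2 * sigma / (r_m * .R_GAS * temperature)
}

# Residuals of the two pressure-balance equations, in mOsm.
# r1: cytoplasm vs medium across the cell surface;
# r2: nucleoplasm vs cytoplasm across the nuclear envelope.
.osmo_residuals <- function(VC, VN, params, Cout) {
  CCy <- params$NCy / (VC - VN - params$bCy)
  CN <- params$NN / (VN - params$bN)
  r1 <- CCy - Cout -
    laplace_concentration_jump(params$sigmaC, VC, params$temperature)
  r2 <- CN - CCy -
    laplace_concentration_jump(params$sigmaN, VN, params$temperature)
  c(r1 = r1, r2 = r2)
}

# For fixed cell volume, the nuclear balance residual has a sign change on
# (bN, VC - bCy): +Inf at the lower end (nucleoplasm infinitely concentrated)
# and -Inf at the upper (cytoplasm infinitely concentrated).
.solve_vn_given_vc <- function(VC, params, Cout, tol) {
  eps <- 1e-9
  lo <- params$bN * (1 + eps) + eps * VC
  hi <- VC - params$bCy * (1 + eps) - eps * VC
  if (hi <= lo)
    stop("free volume collapsed in the nuclear bracket at VC = ",
         format(VC), call. = FALSE)
  f <- function(VN) .osmo_residuals(VC, VN, params, Cout)[["r2"]]
  stats::uniroot(f, lower = lo, upper = hi, tol = 0.01 * tol * VC)$root
}

#' Solve the nested-osmometer steady state
#'
#' Solves the coupled pressure-balance equations for the unique steady-state
#' cell and nuclear volumes: the cytoplasmic concentration exceeds the
#' external one by the Laplace jump of the cell surface, and the
#' nucleoplasmic concentration exceeds the cytoplasmic one by the Laplace
#' jump of the nuclear envelope.  The solver is a nested bisection: for each
#' trial cell volume the nuclear balance is solved by root bracketing, then
#' the outer cell balance is solved the same way.  Uniqueness of the steady
#' state makes this globally convergent without a Jacobian.
#'
#' @param params a [model_params()] object.
#' @param medium a [medium()] object (or a bare positive Cout).
#' @param tol relative tolerance on volumes (default 1e-10).
#' @return an object of class `cell_state`: a list with elements `VC`, `VN`
#'   (um^3), `CCy`, `CN` (mOsm), `nc_ratio`, `residual_norm` (mOsm), plus the
#'   inputs.
#' @examples
#' p <- model_params(NN = 2812.5, NCy = 34687.5, bN = 1.875, bC = 25)
#' st <- solve_steady_state(p, medium(500))
#' st$nc_ratio  # 0.075
#' @export
solve_steady_state <- function(params, medium, tol = 1e-10) {
  stopifnot(inherits(params, "model_params"))
  if (is.numeric(medium)) medium <- medium(medium)
  Cout <- medium$Cout
  scale <- (params$NN + params$NCy) / Cout + params$bC
  lo <- params$bC + 1e-8 * scale
  hi <- 10 * scale
  outer <- function(VC) {
    # a collapsed free volume means an effectively infinite cytoplasmic
    # concentration: report a large positive residual so bisection moves up
    VN <- tryCatch(.solve_vn_given_vc(VC, params, Cout, tol),
                   error = function(e) NA_real_)
    if (is.na(VN)) return(1e12)
    .osmo_residuals(VC, VN, params, Cout)[["r1"]]
  }
  flo <- outer(lo)
  fhi <- outer(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop(sprintf(
      "no steady state bracketed for Cout = %g mOsm on VC in (%.6g, %.6g)",
      Cout, lo, hi), call. = FALSE)
  VC <- stats::uniroot(outer, lower = lo, upper = hi,
                       tol = 0.01 * tol * scale, maxiter = 2000)$root
  # polish with a few extra bisections at fixed relative tolerance
  VN <- .solve_vn_given_vc(VC, params, Cout, tol / 10)
  res <- .osmo_residuals(VC, VN, params, Cout)
  state <- structure(
    list(VC = VC, VN = VN,
         CCy = params$NCy / (VC - VN - params$bCy),
         CN = params$NN / (VN - params$bN),
         nc_ratio = VN / VC,
         residual_norm = max(abs(res)),
         Cout = Cout, params = params),
    class = "cell_state"
  )
  state
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf(
    "Steady state at Cout = %g mOsm: VC = %.4g um^3, VN = %.4g um^3, N/C = %.4f\n",
    x$Cout, x$VC, x$VN, x$nc_ratio))
  cat(sprintf("  CCy = %.4g mOsm, CN = %.4g mOsm, residual = %.3g mOsm\n",
              x$CCy, x$CN, x$residual_norm))
  invisible(x)
}

#' Closed-form N/C ratio in the tension-free, matched-crowding limit
#'
#' When the nuclear envelope is tension-free and the normalized non-osmotic
#' volumes of nucleus and cytoplasm are equal, the steady-state N/C volume
#' ratio reduces to the nuclear share of the osmotically active
#' macromolecules: NN / (NN + NCy).
#'
#' @param params a [model_params()] object, or a list with `NN` and `NCy`.
#' @return the N/C ratio as a dimensionless fraction.
#' @export
nc_ratio_closed_form <- function(params) {
  tot <- params$NN + params$NCy
  if (tot == 0) stop("NN + NCy must be non-zero", call. = FALSE)
  params$NN / tot
}

#' Steady states across a series of external concentrations
#'
#' @param params a [model_params()] object.
#' @param couts numeric vector of external concentrations (mOsm) or a list
#'   of [medium()] objects.
#' @param tol solver tolerance, see [solve_steady_state()].
#' @return a data.frame with one row per concentration: `cout_mosm`,
#'   `vc_um3`, `vn_um3`, `ccy_mosm`, `cn_mosm`, `nc_ratio`, `residual`.
#' @export
shock_response <- function(params, couts, tol = 1e-10) {
  if (is.list(couts)) couts <- vapply(couts, `[[`, numeric(1), "Cout")
  if (length(couts) == 0) stop("`couts` must be non-empty", call. = FALSE)
  rows <- lapply(couts, function(co) {
    st <- tryCatch(solve_steady_state(params, medium(co), tol = tol),
                   error = function(e)
                     stop(sprintf("solver failed at Cout = %g mOsm: %s",
                                  co, conditionMessage(e)), call. = FALSE))
    data.frame(cout_mosm = co, vc_um3 = st$VC, vn_um3 = st$VN,
               ccy_mosm = st$CCy, cn_mosm = st$CN,
               nc_ratio = st$nc_ratio, residual = st$residual_norm)
  })
  do.call(rbind, rows)
}

#' Sensitivity of the N/C ratio to osmotic shocks
#'
#' Sweeps the external concentration and scores the excursion of the N/C
#' ratio as (max - min) / value at the isotonic concentration.  A score of
#' zero means the ratio is perfectly buffered against osmotic shifts.
#'
#' @param params a [model_params()] object.
#' @param cout_range concentrations to sweep (mOsm); must include
#'   `c_iso`.
#' @param c_iso the isotonic concentration (mOsm); defaults to the median of
#'   the sweep.
#' @return non-negative sensitivity score.
#' @export
nc_sensitivity <- function(params, cout_range, c_iso = stats::median(cout_range)) {
  if (!any(abs(cout_range - c_iso) / c_iso < 1e-12))
    cout_range <- sort(c(cout_range, c_iso))
  resp <- shock_response(params, cout_range)
  iso <- resp$nc_ratio[which.min(abs(resp$cout_mosm - c_iso))]
  (max(resp$nc_ratio) - min(resp$nc_ratio)) / iso
}

#' Default external-concentration sweep for sensitivity scans
#'
#' Ciso/Cout from 0.5 to 2 at `n` log-spaced points (hypertonic to
#' hypotonic), mirroring a twofold shock range in either direction.
#'
#' @param c_iso isotonic concentration (mOsm).
#' @param n number of points.
#' @return numeric vector of concentrations including `c_iso`.
#' @export
default_cout_sweep <- function(c_iso = 500, n = 41) {
  ratio <- exp(seq(log(0.5), log(2), length.out = n))
  sort(unique(c(c_iso / ratio, c_iso)))
}

#' Phase diagram of N/C-ratio sensitivity
#'
#' Evaluates [nc_sensitivity()] on a grid of crowding mismatch (ratio of
#' cytoplasmic to nuclear normalized non-osmotic volume) and nuclear
#' envelope tension.  At each grid point the base parameters are re-derived
#' so that the whole-cell non-osmotic volume and osmolyte amounts are kept
#' while `bN` is scaled to produce the requested nu_bC / nu_bN ratio at the
#' isotonic state.
#'
#' @param nub_ratio_grid grid of nu_bC / nu_bN values (dimensionless).
#' @param sigmaN_grid grid of nuclear tensions (N/m).
#' @param base_params a [model_params()] object giving amounts, `bC`,
#'   `sigmaC` and temperature.
#' @param cout_range concentration sweep (mOsm); default
#'   [default_cout_sweep()].
#' @param c_iso isotonic concentration (mOsm).
#' @return an object of class `sensitivity_grid`: list with `axis1`
#'   (nub ratios), `axis2` (sigmaN), `values` (matrix, rows = axis1),
#'   `cout_range`.  Grid points where the solver fails hold `NA` and raise
#'   one warning each.
#' @export
phase_diagram <- function(nub_ratio_grid, sigmaN_grid, base_params,
                          cout_range = default_cout_sweep(c_iso), c_iso = 500) {
  stopifnot(length(nub_ratio_grid) > 0, length(sigmaN_grid) > 0)
  vals <- matrix(NA_real_, nrow = length(nub_ratio_grid),
                 ncol = length(sigmaN_grid))
  for (i in seq_along(nub_ratio_grid)) {
    for (j in seq_along(sigmaN_grid)) {
      p <- .params_with_nub_ratio(base_params, nub_ratio_grid[i],
                                  sigmaN_grid[j], c_iso)
      vals[i, j] <- tryCatch(
        nc_sensitivity(p, cout_range, c_iso = c_iso),
        error = function(e) {
          warning(sprintf("solver failed at nub ratio %g, sigmaN %g: %s",
                          nub_ratio_grid[i], sigmaN_grid[j],
                          conditionMessage(e)), call. = FALSE)
          NA_real_
        })
    }
  }
  structure(list(axis1 = nub_ratio_grid, axis2 = sigmaN_grid,
                 values = vals, cout_range = cout_range, c_iso = c_iso),
            class = "sensitivity_grid")
}

# Choose bN so that nu_bC / nu_bN at the zero-tension isotonic state equals
# `ratio`, holding bC and osmolyte amounts fixed.  With sigma = 0 the
# isotonic volumes are V = b + N/Ciso per compartment, which gives the
# closed form below; ratio = 1 reduces to matched crowding bN = (NN/NCell) bC.
.params_with_nub_ratio <- function(base, ratio, sigmaN, c_iso) {
  NCell <- base$NN + base$NCy
  denom <- ratio * (NCell / c_iso + base$bC) - base$bC
  if (denom <= 0)
    stop("nub ratio ", format(ratio), " not attainable with these amounts",
         call. = FALSE)
  bN <- base$bC * (base$NN / c_iso) / denom
  bN <- min(max(bN, 0), base$bC)
  model_params(NN = base$NN, NCy = base$NCy, bN = bN, bC = base$bC,
               sigmaC = base$sigmaC, sigmaN = sigmaN,
               temperature = base$temperature)
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf(
    "N/C sensitivity grid: %d nub ratios x %d tensions, sweep %d Cout values\n",
    length(x$axis1), length(x$axis2), length(x$cout_range)))
  cat(sprintf("  score range [%.3g, %.3g], %d failed points\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              sum(is.na(x$values))))
  invisible(x)
}
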