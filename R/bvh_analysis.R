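#' Normalize osmotic-shift volume measurements for a Boyle-Van't Hoff plot
#'
#' A Boyle-Van't Hoff (BVH) plot displays normalized volume V/V_iso against
#' normalized inverse external concentration C_iso/C_out.  An ideal
#' osmometer (negligible membrane tension) falls on a straight line of
#' slope 1 - nu_b and intercept nu_b, where nu_b = b/V_iso is the
#' normalized non-osmotic volume.
#'
#' @param records data.frame with columns `cell_id`, `compartment`
#'   (`"cell"` or `"nucleus"`), `c_iso`, `c_out` (same concentration unit
#'   within a group: sorbitol molarity or total mOsm — BVH only uses their
#'   ratio), `v_iso_um3`, `v_um3`, and optionally `group` and `conc_units`.
#' @return data.frame with columns `cell_id`, `compartment`, `group`,
#'   `x` (= C_iso/C_out) and `y` (= V/V_iso).
#' @export
normalize_shift_data <- function(records) {
  need <- c("c_iso", "c_out", "v_iso_um3", "v_um3")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0) stop("`records` is empty", call. = FALSE)
  with(records, {
    if (any(c_iso <= 0 | c_out <= 0))
      stop("concentrations must be positive", call. = FALSE)
    if (any(v_iso_um3 <= 0 | v_um3 <= 0))
      stop("volumes must be positive", call. = FALSE)
  })
  grp <- if ("group" %in% names(records)) records$group
         else rep("all", nrow(records))
  if ("conc_units" %in% names(records)) {
    units_per_group <- tapply(as.character(records$conc_units), grp,
                              function(u) length(unique(u)))
    if (any(units_per_group > 1))
      stop("mixed concentration units within a group", call. = FALSE)
  }
  data.frame(
    cell_id = if ("cell_id" %in% names(records)) records$cell_id
              else seq_len(nrow(records)),
    compartment = if ("compartment" %in% names(records)) records$compartment
                  else "cell",
    group = grp,
    x = records$c_iso / records$c_out,
    y = records$v_um3 / records$v_iso_um3
  )
}

#' Fit the Boyle-Van't Hoff line
#'
#' Ordinary least squares fit of normalized volume on normalized inverse
#' concentration.  The intercept estimates the normalized non-osmotic
#' volume nu_b; for an ideal osmometer the line passes through (1, 1), so
#' slope + intercept should equal 1 within error.  A lack-of-fit test of
#' linearity (see [ideality_test()]) is attached when the design allows it.
#'
#' @param points data.frame with columns `x`, `y` (from
#'   [normalize_shift_data()]).
#' @param through_iso if `TRUE`, constrain the line through (1, 1) and fit
#'   the slope only (intercept reported as 1 - slope).  Default `FALSE`.
#' @return an object of class `bvh_fit`: slope, intercept (= nu_b),
#'   standard errors, `r_squared`, `n_points`, `lack_of_fit_p` (NA when no
#'   test is possible), `ideality_method`, and the underlying `lm` in
#'   `$model`.
#' @export
fit_bvh_linear <- function(points, through_iso = FALSE) {
  x <- points$x
  y <- points$y
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("degenerate design: all x values identical", call. = FALSE)
  if (through_iso) {
    # y - 1 = s (x - 1): one-parameter regression through the isotonic point
    fit <- stats::lm(I(y - 1) ~ 0 + I(x - 1))
    slope <- unname(stats::coef(fit)[1])
    se_s <- sqrt(stats::vcov(fit)[1, 1])
    intercept <- 1 - slope
    se_i <- se_s
  } else {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)["x"])
    intercept <- unname(stats::coef(fit)["(Intercept)"])
    se <- sqrt(diag(stats::vcov(fit)))
    se_s <- unname(se["x"])
    se_i <- unname(se["(Intercept)"])
  }
  idl <- tryCatch(ideality_test(points), error = function(e) NULL,
                  warning = function(w) suppressWarnings(ideality_test(points)))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  out <- structure(
    list(slope = slope, intercept = intercept,
         stderr_slope = se_s, stderr_intercept = se_i,
         r_squared = r2, n_points = length(x),
         lack_of_fit_p = if (is.null(idl)) NA_real_ else idl$p_value,
         ideality_method = if (is.null(idl)) NA_character_ else idl$method,
         through_iso = through_iso, model = fit),
    class = "bvh_fit"
  )
  if (!(out$intercept >= 0 && out$intercept < 1))
    warning(sprintf("fitted nu_b = %.3f lies outside [0, 1)", out$intercept),
            call. = FALSE)
  out
}

#' @export
print.bvh_fit <- function(x, ...) {
  cat(sprintf("BVH fit (n = %d%s)\n", x$n_points,
              if (x$through_iso) ", constrained through (1,1)" else ""))
  cat(sprintf("  slope      = %.4f (SE %.4f)\n", x$slope, x$stderr_slope))
  cat(sprintf("  nu_b (int) = %.4f (SE %.4f)\n", x$intercept,
              x$stderr_intercept))
  cat(sprintf("  R^2 = %.4f, slope + intercept = %.4f\n",
              x$r_squared, x$slope + x$intercept))
  if (!is.na(x$lack_of_fit_p))
    cat(sprintf("  ideality (%s) p = %.3g\n", x$ideality_method,
                x$lack_of_fit_p))
  invisible(x)
}

#' Test ideal-osmometer (linear) behavior
#'
#' Compartments with significant membrane tension deviate from the linear
#' BVH law.  With replicated concentration levels this runs the pure-error
#' lack-of-fit F-test of the linear model; without replication it falls
#' back (with a warning) to a t-test on a quadratic curvature term.  A
#' small p-value rejects ideal-osmometer behavior.
#'
#' @param points data.frame with columns `x`, `y`.
#' @return list with `statistic`, `p_value`, `df`, `method`
#'   (`"lack-of-fit F"` or `"quadratic t"`).
#' @export
ideality_test <- function(points) {
  x <- points$x
  y <- points$y
  xf <- factor(signif(x, 12))
  n_levels <- nlevels(xf)
  replicated <- sum(table(xf) >= 2) >= 2 && n_levels >= 3
  if (replicated) {
    lin <- stats::lm(y ~ x)
    sat <- stats::lm(y ~ xf)
    an <- stats::anova(lin, sat)
    list(statistic = an$F[2], p_value = an$`Pr(>F)`[2],
         df = c(an$Df[2], an$Res.Df[2]), method = "lack-of-fit F")
  } else if (n_levels >= 3) {
    warning("no replicated concentration levels; using quadratic curvature t-test",
            call. = FALSE)
    quad <- stats::lm(y ~ x + I(x^2))
    sm <- stats::summary.lm(quad)$coefficients
    list(statistic = sm["I(x^2)", "t value"],
         p_value = sm["I(x^2)", "Pr(>|t|)"],
         df = stats::df.residual(quad), method = "quadratic t")
  } else if (n_levels == 2 && sum(table(xf) >= 2) >= 2) {
    # two replicated levels: pure error exists but the linear model is
    # saturated in means; compare against the two-means model
    lin <- stats::lm(y ~ x)
    sat <- stats::lm(y ~ xf)
    an <- stats::anova(lin, sat)
    p <- an$`Pr(>F)`[2]
    list(statistic = an$F[2], p_value = ifelse(is.na(p), 1, p),
         df = c(an$Df[2], an$Res.Df[2]), method = "lack-of-fit F")
  } else {
    stop("ideality test needs >= 3 concentration levels or replication",
         call. = FALSE)
  }
}

#' Theoretical BVH response of a single compartment with membrane tension
#'
#' For each external concentration, solves the single-compartment balance
#' (C - Cout) R_gas T = 2 sigma / R with C = N/(V - b) for the volume V and
#' returns the normalized BVH coordinates.  At sigma = 0 this is exactly the
#' linear BVH law y = (1 - nu_b) x + nu_b; with tension the hypotonic branch
#' flattens as swelling is resisted.
#'
#' @param N osmolyte amount (mOsm um^3).
#' @param b non-osmotic volume (um^3).
#' @param sigma membrane tension (N/m).
#' @param c_iso isotonic external concentration (mOsm).
#' @param cout_grid external concentrations to evaluate (mOsm).
#' @param temperature absolute temperature (K).
#' @return data.frame with `cout`, `v_um3`, `x` (= c_iso/cout), `y`
#'   (= V/V_iso); non-converged points are NA with a warning.
#' @export
predict_bvh_curve <- function(N, b, sigma, c_iso, cout_grid,
                              temperature = .DEFAULT_TEMPERATURE) {
  stopifnot(N > 0, b >= 0, sigma >= 0, c_iso > 0, all(cout_grid > 0))
  solve_one <- function(cout) {
    if (sigma == 0) return(b + N / cout)
    f <- function(V) {
      N / (V - b) - cout -
        laplace_concentration_jump(sigma, V, temperature)
    }
    lo <- b + 1e-9 * (b + N / cout)
    hi <- 10 * (b + N / cout)
    tryCatch(stats::uniroot(f, lower = lo, upper = hi, tol = 1e-12 * hi)$root,
             error = function(e) {
               warning(sprintf("no volume solution at Cout = %g", cout),
                       call. = FALSE)
               NA_real_
             })
  }
  v_iso <- solve_one(c_iso)
  v <- vapply(cout_grid, solve_one, numeric(1))
  data.frame(cout = cout_grid, v_um3 = v,
             x = c_iso / cout_grid, y = v / v_iso)
}

#' Infer a cell's osmolyte amount from a paired osmotic shift
#'
#' For an ideal osmometer, N/(V - b) = Cout.  Measuring the same cell's
#' volume before (V1, at internal concentration C1) and after (V2) a known
#' change in external concentration dC determines the only unknown:
#' C1 = dC (V2 - b) / ((V1 - b) - (V2 - b)) and N = C1 (V1 - b).
#'
#' @param V_before volume before the shift (um^3).
#' @param V_after volume after the shift (um^3).
#' @param deltaC external concentration change (mOsm; positive =
#'   hypertonic).
#' @param b non-osmotic volume (um^3), typically nu_b * V_iso with nu_b from
#'   the population BVH fit.
#' @param cell_id optional identifier.
#' @return an object of class `osmolyte_estimate`: `N` (mOsm um^3),
#'   `N_particles`, `C_iso_internal` (mOsm), `b_used`, and a `quality` flag
#'   (`"ok"` or `"inconsistent-sign"`).
#' @export
infer_osmolytes <- function(V_before, V_after, deltaC, b, cell_id = NA) {
  f1 <- V_before - b
  f2 <- V_after - b
  if (f1 <= 0 || f2 <= 0)
    stop("free volume (V - b) must be positive for both measurements",
         call. = FALSE)
  if (V_before == V_after) stop("volumes must differ", call. = FALSE)
  if (deltaC == 0) stop("`deltaC` must be non-zero", call. = FALSE)
  quality <- "ok"
  if (sign(deltaC) == sign(V_after - V_before)) {
    warning("volume changed in the same direction as the external concentration; estimate flagged",
            call. = FALSE)
    quality <- "inconsistent-sign"
  }
  C1 <- deltaC * f2 / (f1 - f2)
  N <- C1 * f1
  structure(list(cell_id = cell_id, N = N,
                 N_particles = particles_from_amount(N),
                 C_iso_internal = C1, b_used = b, quality = quality),
            class = "osmolyte_estimate")
}

#' @export
print.osmolyte_estimate <- function(x, ...) {
  cat(sprintf(
    "Osmolyte estimate%s: N = %.4g mOsm um^3 (%.3g particles), C_iso = %.4g mOsm [%s]\n",
    if (is.na(x$cell_id)) "" else paste0(" (cell ", x$cell_id, ")"),
    x$N, x$N_particles, x$C_iso_internal, x$quality))
  invisible(x)
}
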