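#' Seeded synthetic-data generators
#'
#' Every analysis input the package consumes can be generated synthetically
#' with the statistical structure the analyses assume: osmotic-shift volume
#' tables from the ideal/tense osmometer forward model, GEM particle tracks
#' from Brownian or fractional Brownian motion with localization error,
#' D_eff-vs-concentration tables from the Phillies law, and growing-cell
#' cohorts with division-asymmetry-driven N/C dispersion.  All generators
#' take an explicit integer seed and are deterministic given it.
#'
#' @name synthetic-data
#' @keywords internal
NULL

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# multiplicative lognormal noise with unit mean and given CV
.mult_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate an osmotic-shift volume dataset
#'
#' Simulates a protoplast-style osmotic-shift experiment: cells with
#' lognormal size heterogeneity are shifted from an isotonic medium to a
#' range of sorbitol-equivalent concentrations, and their post-shift
#' volumes follow the single-compartment osmometer forward model
#' ([predict_bvh_curve()]): exactly the linear BVH law when `sigma = 0`,
#' tension-flattened otherwise.  Measured volumes carry multiplicative
#' lognormal noise.
#'
#' @param seed integer seed.
#' @param n_cells number of cells (default 400).
#' @param nub normalized non-osmotic volume (default 0.25).
#' @param sigma membrane tension (N/m, default 0: ideal osmometer).
#' @param c_iso isotonic concentration (M-sorbitol equivalent, default
#'   0.4).
#' @param conc_levels shift concentrations (default 0.2 to 1.0 M by 0.2);
#'   must include `c_iso`.
#' @param mean_v_iso mean isotonic cell volume (um^3, default 100).
#' @param size_cv lognormal CV of isotonic volumes (default 0.3).
#' @param noise_cv multiplicative measurement noise CV (default 0.05).
#' @param paired if `TRUE`, emit one before/after pair per cell (for
#'   [infer_osmolytes()]); cells are assigned round-robin to the non-iso
#'   levels.  If `FALSE` (default) each cell contributes one post-shift
#'   record at a round-robin level plus its isotonic record.
#' @param compartment label for the records (default `"cell"`).
#' @return data.frame in the shift-record schema: `cell_id`,
#'   `compartment`, `group`, `c_iso`, `c_out`, `conc_units`, `v_iso_um3`,
#'   `v_um3` (and `v_before_um3`, `delta_c` when `paired`).
#' @export
gen_shift_dataset <- function(seed, n_cells = 400, nub = 0.25, sigma = 0,
                              c_iso = 0.4,
                              conc_levels = seq(0.2, 1.0, by = 0.2),
                              mean_v_iso = 100, size_cv = 0.3,
                              noise_cv = 0.05, paired = FALSE,
                              compartment = "cell") {
  if (!any(abs(conc_levels - c_iso) < 1e-12))
    stop("`conc_levels` must include the isotonic level", call. = FALSE)
  stopifnot(nub >= 0, nub < 1, sigma >= 0, n_cells > 0)
  .with_seed(seed, {
    sdlog <- sqrt(log(1 + size_cv^2))
    v_iso_true <- stats::rlnorm(n_cells, meanlog = log(mean_v_iso) - sdlog^2 / 2,
                                sdlog = sdlog)
    levels_use <- conc_levels
    if (!paired)
      levels_use <- conc_levels[abs(conc_levels - c_iso) >= 1e-12]
    if (length(levels_use) == 0) levels_use <- conc_levels
    c_out <- levels_use[(seq_len(n_cells) - 1L) %% length(levels_use) + 1L]
    # forward model per cell (concentrations to mOsm for the tension term)
    v_true <- vapply(seq_len(n_cells), function(i) {
      b <- nub * v_iso_true[i]
      if (sigma == 0) {
        # ideal: V = b + (V_iso - b) * c_iso / c_out
        b + (v_iso_true[i] - b) * c_iso / c_out[i]
      } else {
        N <- (c_iso * 1000 +
                laplace_concentration_jump(sigma, v_iso_true[i])) *
          (v_iso_true[i] - b)
        curve <- predict_bvh_curve(N, b, sigma, c_iso * 1000,
                                   c_out[i] * 1000)
        curve$v_um3[1]
      }
    }, numeric(1))
    v_iso_meas <- v_iso_true * .mult_noise(n_cells, noise_cv)
    v_meas <- v_true * .mult_noise(n_cells, noise_cv)
    out <- data.frame(
      cell_id = seq_len(n_cells), compartment = compartment,
      group = "synthetic", c_iso = c_iso, c_out = c_out,
      conc_units = "M-sorbitol", v_iso_um3 = v_iso_meas, v_um3 = v_meas)
    if (paired) {
      out$v_before_um3 <- v_iso_meas
      out$delta_c <- (c_out - c_iso) * 1000  # mOsm
    }
    out
  })
}

#' Generate Brownian GEM tracks
#'
#' Two-dimensional Brownian trajectories with Gaussian increments of
#' per-axis variance 2 D dt, optionally corrupted by static localization
#' error (iid Gaussian of SD `loc_sd` added to every position, which
#' offsets the MSD by 4 loc_sd^2).
#'
#' @param seed integer seed.
#' @param D diffusion coefficient (um^2/s).
#' @param dt frame interval (s, default 0.01 = 100 Hz).
#' @param duration track duration (s, default 10).
#' @param n_tracks number of tracks (default 100).
#' @param loc_sd localization error SD (um, default 0.03; set 0 for exact
#'   Brownian positions).
#' @return data.frame in the track schema: `track_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`; attribute `dt_s` records the frame interval.
#' @export
gen_brownian_tracks <- function(seed, D, dt = 0.01, duration = 10,
                                n_tracks = 100, loc_sd = 0.03) {
  stopifnot(D >= 0, dt > 0, duration > dt, n_tracks > 0, loc_sd >= 0)
  n_frames <- floor(duration / dt) + 1L
  .with_seed(seed, {
    step_sd <- sqrt(2 * D * dt)
    per_track <- lapply(seq_len(n_tracks), function(id) {
      x <- cumsum(c(0, stats::rnorm(n_frames - 1L, 0, step_sd)))
      y <- cumsum(c(0, stats::rnorm(n_frames - 1L, 0, step_sd)))
      if (loc_sd > 0) {
        x <- x + stats::rnorm(n_frames, 0, loc_sd)
        y <- y + stats::rnorm(n_frames, 0, loc_sd)
      }
      data.frame(track_id = id, frame = seq_len(n_frames) - 1L,
                 t_s = (seq_len(n_frames) - 1L) * dt, x_um = x, y_um = y)
    })
    out <- do.call(rbind, per_track)
    attr(out, "dt_s") <- dt
    out
  })
}

# Exact fractional Gaussian noise by Davies-Harte circulant embedding.
# Returns an n-vector of increments with Hurst H and unit variance per
# step; multiply by the desired step SD.  The eigenvalue vector depends
# only on (n, H) and is cached by the caller for speed.
.fgn_eigenvalues <- function(n, H) {
  k <- 0:(n - 1)
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  first_row <- c(g, 0, rev(g[-1]))
  ev <- Re(stats::fft(first_row))
  if (min(ev) < -1e-8 * max(ev))
    stop("circulant embedding not non-negative definite", call. = FALSE)
  pmax(ev, 0)
}

.fgn_draw <- function(ev, n) {
  m <- length(ev)  # 2n
  z <- stats::rnorm(m)
  z2 <- stats::rnorm(m)
  # build the complex vector with the required Hermitian structure
  w <- complex(real = z, imaginary = z2)
  f <- stats::fft(sqrt(ev) * w) / sqrt(m)
  Re(f)[seq_len(n)]
}

#' Generate fractional-Brownian-motion GEM tracks
#'
#' Subdiffusive trajectories with exact fractional Gaussian increments
#' (Davies-Harte circulant embedding, exact covariance), Hurst parameter
#' H = alpha/2, so the ensemble MSD follows 4 D_scale tau^alpha.
#' `alpha = 1` reduces to Brownian motion.
#'
#' @param seed integer seed.
#' @param D_scale generalized diffusivity (um^2/s^alpha); the per-axis
#'   variance at lag tau is 2 D_scale tau^alpha.
#' @param alpha anomalous exponent in (0, 2).
#' @param dt frame interval (s).
#' @param duration track duration (s).
#' @param n_tracks number of tracks.
#' @param loc_sd localization error SD (um).
#' @return data.frame in the track schema (as [gen_brownian_tracks()]).
#' @export
gen_fbm_tracks <- function(seed, D_scale, alpha, dt = 0.01, duration = 10,
                           n_tracks = 100, loc_sd = 0.03) {
  if (alpha <= 0 || alpha >= 2)
    stop("`alpha` must be in (0, 2)", call. = FALSE)
  stopifnot(D_scale > 0, dt > 0, duration > dt, n_tracks > 0, loc_sd >= 0)
  H <- alpha / 2
  n_steps <- floor(duration / dt)
  step_sd <- sqrt(2 * D_scale * dt^alpha)  # per-axis increment SD
  ev <- .fgn_eigenvalues(n_steps, H)
  .with_seed(seed, {
    per_track <- lapply(seq_len(n_tracks), function(id) {
      x <- cumsum(c(0, step_sd * .fgn_draw(ev, n_steps)))
      y <- cumsum(c(0, step_sd * .fgn_draw(ev, n_steps)))
      if (loc_sd > 0) {
        x <- x + stats::rnorm(n_steps + 1L, 0, loc_sd)
        y <- y + stats::rnorm(n_steps + 1L, 0, loc_sd)
      }
      data.frame(track_id = id, frame = 0:n_steps,
                 t_s = (0:n_steps) * dt, x_um = x, y_um = y)
    })
    out <- do.call(rbind, per_track)
    attr(out, "dt_s") <- dt
    out
  })
}

#' Generate a growing-cell cohort with N/C-ratio dispersion
#'
#' Emulates time-lapse measurements of asymmetrically dividing cells
#' (pom1-delta-like): mother cells at division have N/C ratio f0 and
#' lognormal size dispersion; mitosis splits the nucleus evenly but places
#' the septum asymmetrically, so a daughter receiving volume fraction `a`
#' is born with nc0 = f0 / (2a).  Daughters then grow per the exponential
#' (or linear) growth model and both volumes carry multiplicative
#' measurement noise at every timepoint.
#'
#' The default asymmetry SD (0.1 on the volume fraction, i.e. CV 0.2)
#' makes the cohort's nc0 standard deviation threefold the
#' symmetric-division case given 5% volume noise:
#' sqrt(3^2 - 1) * sqrt(2) * 0.05 = 0.2.
#'
#' @param seed integer seed.
#' @param n_cells number of daughter cells (default 200).
#' @param gammaC exponential growth rate (min^-1, default 0.006).
#' @param f0 equilibrium N/C ratio (default 0.075).
#' @param t_grid sampling times (min, default 0 to 40 by 4).
#' @param division_asymmetry SD of the daughter volume fraction around 0.5
#'   (default 0.1; 0 gives symmetric, WT-like divisions).  Fractions are
#'   truncated to [0.25, 0.75].
#' @param mean_birth_volume mean daughter volume at birth (um^3, default
#'   100).
#' @param size_cv lognormal CV of mother sizes (default 0.15).
#' @param noise_cv measurement noise CV on each volume (default 0.05).
#' @param mode growth mode, `"exponential"` (default) or `"linear"`.
#' @return trajectory data.frame: `cell_id`, `t_min`, `vc_um3`, `vn_um3`,
#'   `nc`, `mitotic` (all FALSE).
#' @export
gen_homeostasis_population <- function(seed, n_cells = 200, gammaC = 0.006,
                                       f0 = 0.075,
                                       t_grid = seq(0, 40, by = 4),
                                       division_asymmetry = 0.1,
                                       mean_birth_volume = 100,
                                       size_cv = 0.15, noise_cv = 0.05,
                                       mode = "exponential") {
  stopifnot(n_cells > 0, division_asymmetry >= 0)
  .with_seed(seed, {
    sdlog <- sqrt(log(1 + size_cv^2))
    mother_v <- stats::rlnorm(n_cells,
                              meanlog = log(2 * mean_birth_volume) - sdlog^2 / 2,
                              sdlog = sdlog)
    a <- if (division_asymmetry > 0)
      pmin(pmax(stats::rnorm(n_cells, 0.5, division_asymmetry), 0.25), 0.75)
    else rep(0.5, n_cells)
    vc0 <- a * mother_v
    vn0 <- f0 * mother_v / 2  # nuclei split evenly
    rows <- lapply(seq_len(n_cells), function(i) {
      tr <- simulate_growth(vc0[i], vn0[i], gammaC, f0, t_grid,
                            mode = mode, cell_id = i)
      n_t <- nrow(tr)
      tr$vc_um3 <- tr$vc_um3 * .mult_noise(n_t, noise_cv)
      tr$vn_um3 <- tr$vn_um3 * .mult_noise(n_t, noise_cv)
      tr$nc <- tr$vn_um3 / tr$vc_um3
      tr
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a D_eff-versus-concentration dataset
#'
#' D values follow the Phillies law D0 exp(-beta C^lambda) with
#' multiplicative lognormal noise, at a set of concentrations.
#'
#' @param seed integer seed.
#' @param D0 dilute-limit diffusivity (um^2/s, default 13.9: a 40-nm
#'   sphere in water at 30 C).
#' @param beta concentration coefficient (default 2, in the chosen
#'   concentration unit^-lambda).
#' @param lam stretching exponent (default 1).
#' @param conc_levels concentrations (default 0.2 to 1.6 by 0.2).
#' @param n_per_level replicate D measurements per concentration
#'   (default 20).
#' @param noise_cv multiplicative noise CV (default 0.1).
#' @return data.frame with `conc`, `deff`.
#' @export
gen_phillies_dataset <- function(seed, D0 = 13.9, beta = 2, lam = 1,
                                 conc_levels = seq(0.2, 1.6, by = 0.2),
                                 n_per_level = 20, noise_cv = 0.1) {
  stopifnot(D0 > 0, beta >= 0, n_per_level > 0)
  .with_seed(seed, {
    conc <- rep(conc_levels, each = n_per_level)
    d_true <- D0 * exp(-beta * conc^lam)
    data.frame(conc = conc,
               deff = d_true * .mult_noise(length(conc), noise_cv))
  })
}
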