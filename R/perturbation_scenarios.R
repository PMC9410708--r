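#' Schedule of solute redistribution and synthesis modulation
#'
#' Describes a perturbation as two time courses: the cumulative fraction of
#' the cytoplasmic osmolyte pool moved into the nucleus (emulating a
#' nuclear-export block such as leptomycin B), and a multiplicative factor
#' on the biosynthesis rate (emulating translation inhibition such as
#' cycloheximide).  The default transfer shape is a linear ramp.
#'
#' @param duration total simulated time (min).
#' @param dt time step (min).
#' @param transfer_total cumulative transfer fraction reached at
#'   `duration` (in [0, 1)).
#' @param transfer_fn optional function(t) returning the cumulative
#'   transfer fraction; overrides the linear ramp.  Must be non-decreasing
#'   with values in [0, 1).
#' @param synthesis_fn function(t) returning the synthesis modifier
#'   (>= 0); default constantly 1.
#' @return object of class `redistribution_schedule`.
#' @export
redistribution_schedule <- function(duration = 60, dt = 1,
                                    transfer_total = 0,
                                    transfer_fn = NULL,
                                    synthesis_fn = function(t) rep(1, length(t))) {
  stopifnot(duration > 0, dt > 0)
  if (is.null(transfer_fn)) {
    if (transfer_total < 0 || transfer_total >= 1)
      stop("`transfer_total` must be in [0, 1)", call. = FALSE)
    transfer_fn <- function(t) transfer_total * pmin(pmax(t / duration, 0), 1)
  }
  tt <- seq(0, duration, by = dt)
  fr <- transfer_fn(tt)
  if (any(diff(fr) < -1e-12) || any(fr < 0) || any(fr >= 1))
    stop("transfer fraction must be non-decreasing within [0, 1)",
         call. = FALSE)
  sm <- synthesis_fn(tt)
  if (any(sm < 0)) stop("synthesis modifier must be >= 0", call. = FALSE)
  structure(list(times = tt, transfer_fraction = fr,
                 synthesis_modifier = sm, duration = duration, dt = dt),
            class = "redistribution_schedule")
}

#' Simulate solute redistribution into the nucleus
#'
#' Discrete-time simulation of a growing cell whose cytoplasmic osmolytes
#' are progressively transferred into the nucleus.  At each step,
#' biosynthesis adds osmolytes at relative rate gammaC x modifier (a
#' fraction f0 of new material routed to the nucleus, dry volume added pro
#' rata), the scheduled increment of the cytoplasmic pool is moved across
#' the envelope, and the nested-osmometer steady state is re-solved.
#' Transfer conserves the total osmolyte amount exactly.  With
#' matched-crowding bookkeeping (default), dry volume accompanies the
#' transferred solutes in proportion, keeping the normalized non-osmotic
#' volumes equal on the two sides of the envelope, as observed under
#' export block.
#'
#' @param params initial [model_params()].
#' @param schedule a [redistribution_schedule()].  Its transfer fraction is
#'   applied incrementally: between consecutive times a fraction
#'   `diff(transfer_fraction)` of the current cytoplasmic pool moves.
#' @param gammaC growth rate (min^-1); set 0 to isolate the transfer
#'   effect.
#' @param f0 nuclear fraction of synthesis.
#' @param Cout external concentration (mOsm).
#' @param move_dry_volume if `TRUE` (default) dry volume accompanies
#'   transferred solutes pro rata.
#' @return data.frame: `t_min`, `vc_um3`, `vn_um3`, `nc`, `ccy_mosm`,
#'   `cn_mosm`, `nn`, `ncy`, `residual`.
#' @export
simulate_redistribution <- function(params, schedule, gammaC = 0.006,
                                    f0 = 0.075, Cout = 500,
                                    move_dry_volume = TRUE) {
  stopifnot(inherits(params, "model_params"),
            inherits(schedule, "redistribution_schedule"))
  tt <- schedule$times
  NN <- params$NN; NCy <- params$NCy
  bN <- params$bN; bCy <- params$bCy
  rows <- vector("list", length(tt))
  for (i in seq_along(tt)) {
    if (i > 1) {
      h <- tt[i] - tt[i - 1]
      mod <- schedule$synthesis_modifier[i - 1]
      # biosynthesis, partitioned f0 / (1 - f0); dry volume tracks amounts
      dN <- gammaC * mod * (NN + NCy) * h
      db <- if (NN + NCy > 0) (bN + bCy) / (NN + NCy) * dN else 0
      NN <- NN + f0 * dN
      NCy <- NCy + (1 - f0) * dN
      bN <- bN + f0 * db
      bCy <- bCy + (1 - f0) * db
      # scheduled transfer of the current cytoplasmic pool
      dF <- schedule$transfer_fraction[i] - schedule$transfer_fraction[i - 1]
      moved <- dF * NCy
      if (move_dry_volume && NCy > 0) {
        b_moved <- moved * bCy / NCy
        bN <- bN + b_moved
        bCy <- bCy - b_moved
      }
      NN <- NN + moved
      NCy <- NCy - moved
    }
    p <- model_params(NN = NN, NCy = NCy, bN = bN, bC = bN + bCy,
                      sigmaC = params$sigmaC, sigmaN = params$sigmaN,
                      temperature = params$temperature)
    st <- tryCatch(solve_steady_state(p, medium(Cout)),
                   error = function(e)
                     stop(sprintf("solver failed at t = %g min: %s",
                                  tt[i], conditionMessage(e)), call. = FALSE))
    rows[[i]] <- data.frame(t_min = tt[i], vc_um3 = st$VC, vn_um3 = st$VN,
                            nc = st$nc_ratio, ccy_mosm = st$CCy,
                            cn_mosm = st$CN, nn = NN, ncy = NCy,
                            residual = st$residual_norm)
  }
  do.call(rbind, rows)
}

#' Uniform dilution of both osmolyte pools
#'
#' Scales the nuclear and cytoplasmic osmolyte amounts by the same factor
#' (emulating a uniform slowdown of biosynthesis relative to volume, as
#' under translation inhibition) and re-solves the steady state.  In the
#' tension-free matched-crowding limit the N/C ratio depends only on the
#' ratio of amounts and is exactly invariant under this scaling.
#'
#' @param params a [model_params()].
#' @param dilution_factor factor in (0, 1] applied to both `NN` and `NCy`.
#' @param Cout external concentration (mOsm).
#' @param scale_dry_volume if `TRUE` (default) non-osmotic volumes scale by
#'   the same factor, mirroring the loss of dry mass.
#' @return list with `before` and `after` `cell_state` objects.
#' @export
simulate_uniform_dilution <- function(params, dilution_factor, Cout = 500,
                                      scale_dry_volume = TRUE) {
  stopifnot(inherits(params, "model_params"))
  if (dilution_factor <= 0 || dilution_factor > 1)
    stop("`dilution_factor` must be in (0, 1]", call. = FALSE)
  before <- solve_steady_state(params, medium(Cout))
  s <- dilution_factor
  p2 <- model_params(NN = params$NN * s, NCy = params$NCy * s,
                     bN = if (scale_dry_volume) params$bN * s else params$bN,
                     bC = if (scale_dry_volume) params$bC * s else params$bC,
                     sigmaC = params$sigmaC, sigmaN = params$sigmaN,
                     temperature = params$temperature)
  after <- solve_steady_state(p2, medium(Cout))
  list(before = before, after = after)
}
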