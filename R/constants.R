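#' Physical constants and unit helpers
#'
#' The package works in a fixed unit system chosen so that the osmotic
#' balance arithmetic is exact and the Laplace pressure term stays in SI:
#' concentrations in mOsm (identical to mol/m^3), volumes in um^3, membrane
#' tensions in N/m, temperature in K.  Osmolyte *amounts* are carried as
#' concentration x volume, i.e. mOsm um^3; one mOsm corresponds to
#' 6.02214076e5 particles per um^3.
#'
#' @name osmoscale-units
#' @keywords internal
NULL

# J/(mol K)
.R_GAS <- 8.314462618

# particles per um^3 at 1 mOsm (Avogadro x 1e-3 mol/m^3 x 1e-18 m^3/um^3)
.PARTICLES_PER_MOSM_UM3 <- 6.02214076e5

# J/K
.K_BOLTZMANN <- 1.380649e-23

# default experimental temperature: 30 degrees C
.DEFAULT_TEMPERATURE <- 303.15

#' Convert a particle number density to an osmolarity
#'
#' @param n_per_um3 particle number density (particles/um^3); must be >= 0.
#' @return osmolarity in mOsm (= mol/m^3).
#' @examples
#' osmolarity_from_density(30e7)  # ~498 mOsm, the fission-yeast cytoplasm
#' @export
osmolarity_from_density <- function(n_per_um3) {
  if (!is.numeric(n_per_um3) || any(n_per_um3 < 0))
    stop("`n_per_um3` must be non-negative", call. = FALSE)
  n_per_um3 / .PARTICLES_PER_MOSM_UM3
}

#' Convert an osmolyte amount (mOsm um^3) to a particle count
#'
#' @param amount_mosm_um3 osmolyte amount in concentration x volume units.
#' @return number of particles.
#' @export
particles_from_amount <- function(amount_mosm_um3) {
  amount_mosm_um3 * .PARTICLES_PER_MOSM_UM3
}

#' Surface-area ratio of a sphere from its volume ratio
#'
#' For a sphere, area scales as volume^(2/3).  Used to compare a measured
#' relative surface-area change of the nuclear envelope against the
#' spherical expectation for a given relative volume change.
#'
#' @param volume_ratio ratio of volumes (dimensionless, > 0).
#' @return the corresponding area ratio, `volume_ratio^(2/3)`.
#' @examples
#' sphere_area_ratio(1.40)  # a 40% swelling implies ~25% more area
#' @export
sphere_area_ratio <- function(volume_ratio) {
  if (!is.numeric(volume_ratio) || any(volume_ratio <= 0))
    stop("`volume_ratio` must be positive", call. = FALSE)
  volume_ratio^(2 / 3)
}
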