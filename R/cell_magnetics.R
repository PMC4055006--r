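#' Specify an SPIO-labeled cell
#'
#' A labeled mesenchymal stem cell is reduced to a sphere of diameter
#' `diameter` carrying `iron_mass` of elemental iron as intracellular
#' magnetite, treated as a point dipole at the cell center. The moment is
#' either fully saturated (`"saturated"`, appropriate above ~0.1 T) or
#' follows the Langevin field dependence of the individual SPIO particles
#' (`"langevin"`).
#'
#' @param diameter Cell diameter in meters (default 19.3 um, the mean of the
#'   labeled population).
#' @param iron_mass Elemental iron load in kg (default 21.77 pg).
#' @param moment_model `"saturated"` or `"langevin"`.
#' @param label Optional identifier.
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(diameter = 19.3e-6, iron_mass = 21.77e-15,
                      moment_model = c("saturated", "langevin"),
                      label = NULL) {
  moment_model <- match.arg(moment_model)
  stopifnot(is.numeric(diameter), length(diameter) == 1L, diameter > 0,
            is.numeric(iron_mass), length(iron_mass) == 1L)
  if (iron_mass < 0) stop("'iron_mass' must be non-negative")
  structure(list(diameter = diameter, iron_mass = iron_mass,
                 moment_model = moment_model, label = label),
            class = "cell_spec")
}

#' Specify the suspending fluid
#'
#' @param viscosity Dynamic viscosity in Pa s (default 1.0 mPa s, culture
#'   medium at body temperature treated as water).
#' @param density Fluid density in kg/m^3 (default 1000; cells are taken as
#'   density matched, so buoyancy is neglected).
#' @param temperature Temperature in degrees Celsius (annotation; also sets
#'   the thermal energy of the Langevin moment model).
#' @return An object of class `fluid_spec`.
#' @export
fluid_spec <- function(viscosity = 1.0e-3, density = 1000, temperature = 37) {
  stopifnot(viscosity > 0, density > 0)
  structure(list(viscosity = viscosity, density = density,
                 temperature = temperature), class = "fluid_spec")
}

# saturated moment of the intracellular magnetite load
.saturation_moment <- function(iron_mass) {
  iron_mass * FE_TO_MAGNETITE / MAGNETITE_DENSITY * MAGNETITE_MS
}

# Langevin parameter per tesla for one SPIO particle at temperature T (K)
.xi_per_tesla <- function(temperature_K) {
  mp <- MAGNETITE_MS * pi / 6 * SPIO_DIAMETER^3
  mp / (BOLTZMANN * temperature_K)
}

#' Magnetic moment of a labeled cell
#'
#' Converts the elemental iron load to magnetite
#' (`m(Fe3O4) = m(Fe) * 231.53 / (3 * 55.845)`), to magnetite volume via the
#' density 5180 kg/m^3, and to a saturated moment with the magnetite
#' saturation magnetization 4.8e5 A/m. Under the `"langevin"` model the
#' saturated moment is scaled by the Langevin function `L(xi) = coth(xi) -
#' 1/xi` with `xi = m_p |B| / (kB T)` and `m_p` the moment of a single
#' 62-nm SPIO particle; the result is monotone in `|B|` and capped at the
#' saturated value.
#'
#' @param cell A [cell_spec()].
#' @param B_mag Field magnitudes in tesla (vectorized).
#' @param temperature Temperature in kelvin (default 310.15 K).
#' @return Magnetic moments in A m^2, same length as `B_mag`.
#' @examples
#' cell_moment(cell_spec(), 0.45)  # ~2.79e-12 A m^2
#' @export
cell_moment <- function(cell, B_mag, temperature = 310.15) {
  stopifnot(inherits(cell, "cell_spec"), is.numeric(B_mag))
  if (any(B_mag < 0)) stop("'B_mag' must be non-negative")
  msat <- .saturation_moment(cell$iron_mass)
  if (cell$moment_model == "saturated") return(rep_len(msat, length(B_mag)))
  xi <- .xi_per_tesla(temperature) * B_mag
  L <- ifelse(xi < 1e-6, xi / 3, 1 / tanh(xi) - 1 / xi)
  msat * L
}

#' Magnetophoretic force on a labeled cell
#'
#' Point-dipole force with the moment aligned to the local field:
#' `F = m(|B|) * grad|B|`, directed along the gradient of the field
#' magnitude. The radial attraction component `Fr` is reported in the
#' magnet's `(r, z)` frame, positive toward the magnet axis; it vanishes on
#' the axis by symmetry.
#'
#' @param cell A [cell_spec()].
#' @param fs A `field_sample` from [gradient_at()] (must carry the gradient).
#' @param temperature Kelvin, passed to [cell_moment()].
#' @return A `force_sample` list: `point`, `F` (n x 3, newtons), `F_mag`,
#'   `Fr` (newtons, toward the axis), `moment` (A m^2).
#' @export
magnetic_force <- function(cell, fs, temperature = 310.15) {
  stopifnot(inherits(cell, "cell_spec"), inherits(fs, "field_sample"))
  if (is.null(fs$dBmag))
    stop("'fs' carries no gradient; use gradient_at(), not field_at()")
  m <- cell_moment(cell, fs$B_mag, temperature)
  F <- fs$dBmag * m
  Fr <- if (!is.null(fs$rhat)) -rowSums(F * fs$rhat) else rep(NA_real_, nrow(F))
  structure(list(point = fs$point, F = F, F_mag = sqrt(rowSums(F^2)),
                 Fr = Fr, moment = m), class = "force_sample")
}

#' Stokes drift velocity of a forced cell
#'
#' Overdamped (inertia-free) force balance against Stokes drag on a sphere:
#' `v = F / (3 pi eta d)`.
#'
#' @param cell A [cell_spec()].
#' @param force A `force_sample` from [magnetic_force()], or an `n x 3`
#'   matrix of forces in newtons.
#' @param fluid A [fluid_spec()].
#' @return An `n x 3` matrix of drift velocities in m/s.
#' @export
drift_velocity <- function(cell, force, fluid = fluid_spec()) {
  stopifnot(inherits(cell, "cell_spec"), inherits(fluid, "fluid_spec"))
  if (cell$diameter <= 0) stop("cell diameter must be positive")
  F <- if (inherits(force, "force_sample")) force$F else .as_points(force)
  F / (3 * pi * fluid$viscosity * cell$diameter)
}
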