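#' Tube geometry for the flow-capture experiment
#'
#' The bench configuration is a straight quartz tube with the magnet cylinder
#' pressed against its outer wall at the midsegment, so the pole face sits
#' one wall thickness from the lumen (about 1 mm, the working height of the
#' field model). Lab frame: the tube axis is the x axis, the lumen spans
#' `x` in `[0, length]`, and the magnet sits below at negative y with its
#' axis along +y.
#'
#' @param inner_radius Lumen radius in meters (default 1.15 mm, a 2.3-mm ID
#'   tube).
#' @param wall_thickness Wall thickness in meters (default 1.0 mm, from a
#'   4.3-mm OD).
#' @param length Tube length in meters (default 20 mm).
#' @param magnet_axial_position Axial position of the magnet axis (default
#'   the midsegment, 10 mm).
#' @return An object of class `tube_geometry`.
#' @export
tube_geometry <- function(inner_radius = 1.15e-3, wall_thickness = 1.0e-3,
                          length = 20e-3, magnet_axial_position = 10e-3) {
  stopifnot(inner_radius > 0, wall_thickness >= 0, length > 0,
            magnet_axial_position >= 0, magnet_axial_position <= length)
  structure(list(inner_radius = inner_radius,
                 wall_thickness = wall_thickness, length = length,
                 magnet_axial_position = magnet_axial_position),
            class = "tube_geometry")
}

#' Flow specification
#'
#' @param mean_velocity Cross-section mean axial velocity in m/s.
#' @param profile `"poiseuille"` (laminar parabolic) or `"plug"` (uniform).
#' @return An object of class `flow_spec`.
#' @export
flow_spec <- function(mean_velocity, profile = c("poiseuille", "plug")) {
  profile <- match.arg(profile)
  stopifnot(is.numeric(mean_velocity), length(mean_velocity) == 1L,
            mean_velocity > 0)
  structure(list(mean_velocity = mean_velocity, profile = profile),
            class = "flow_spec")
}

#' Axial velocity profile in the tube
#'
#' Laminar Poiseuille profile `v(rho) = 2 vbar (1 - (rho/R)^2)`, or the
#' uniform plug value.
#'
#' @param rho Radial offsets from the tube axis in meters.
#' @param flow A [flow_spec()].
#' @param tube A [tube_geometry()].
#' @return Axial velocities in m/s.
#' @export
poiseuille_velocity <- function(rho, flow, tube) {
  stopifnot(inherits(flow, "flow_spec"), inherits(tube, "tube_geometry"))
  if (any(rho < 0 | rho > tube$inner_radius))
    stop("'rho' must lie within [0, inner_radius]")
  if (flow$profile == "plug") return(rep_len(flow$mean_velocity, length(rho)))
  2 * flow$mean_velocity * (1 - (rho / tube$inner_radius)^2)
}

#' Default magnet pose against the tube wall
#'
#' Places the pole face tangent to the outer tube wall at the magnet's axial
#' position, axis perpendicular to the tube pointing into the fluid (+y).
#'
#' @param tube A [tube_geometry()].
#' @param magnet A [magnet_spec()]; its dimensions and remanence are kept.
#' @return A repositioned `magnet_spec`.
#' @export
magnet_at_tube <- function(tube, magnet = magnet_spec()) {
  stopifnot(inherits(tube, "tube_geometry"), inherits(magnet, "magnet_spec"))
  magnet$origin <- c(tube$magnet_axial_position,
                     -(tube$inner_radius + tube$wall_thickness), 0)
  magnet$axis <- c(0, 1, 0)
  magnet
}

# Build the flat config list consumed by the compiled integrator.
.sim_config <- function(flow, tube, magnet, rtol, atol, max_step_disp,
                        max_steps, grad_h, footprint_radius, field_stub) {
  if (is.null(footprint_radius)) footprint_radius <- 2 * magnet$radius
  if (is.null(field_stub)) {
    field_type <- 0L
    grad_stub <- c(0, 0, 0)
    stub_bmag <- 0
  } else {
    field_type <- 1L
    grad_stub <- as.numeric(field_stub$grad)
    stub_bmag <- as.numeric(field_stub$bmag %||% 0.45)
  }
  cd <- -magnet$axis
  cd[1] <- 0
  ncd <- sqrt(sum(cd^2))
  cd <- if (ncd > 0) cd / ncd else c(0, -1, 0)
  list(tube_radius = tube$inner_radius, tube_length = tube$length,
       magnet_origin = magnet$origin, magnet_axis = magnet$axis,
       magnet_radius = magnet$radius, magnet_length = magnet$length,
       remanence = magnet$remanence, edge_margin = magnet$edge_margin,
       mean_velocity = flow$mean_velocity,
       profile = if (flow$profile == "plug") 1L else 0L,
       field_type = field_type, grad_stub = grad_stub, stub_bmag = stub_bmag,
       footprint_radius = footprint_radius, capture_dir = cd,
       rtol = rtol, atol = atol, max_step_disp = max_step_disp,
       max_steps = as.integer(max_steps), grad_h = grad_h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fate_labels <- c("exited", "captured", "flagged")

#' Integrate a single cell trajectory
#'
#' Overdamped kinematics `dx/dt = v_flow(x) + v_drift(x)` integrated with an
#' adaptive embedded Runge-Kutta scheme until the cell surface touches the
#' lumen wall inside the magnet footprint (captured, absorbed), the cell
#' leaves the tube (`exited`), or the step budget is exhausted (`flagged`).
#' Wall contacts outside the footprint let the cell continue sliding along
#' the wall.
#'
#' @param cell A [cell_spec()].
#' @param inlet Length-3 lab position inside the lumen at the inlet.
#' @param flow,tube,fluid Flow, tube and fluid specifications.
#' @param magnet A [magnet_spec()]; by default repositioned against the tube
#'   with [magnet_at_tube()] unless `reposition = FALSE`.
#' @param rtol Relative tolerance of the adaptive integrator.
#' @param footprint_radius Capture footprint: maximum lateral distance of a
#'   wall contact from the magnet axis (default one magnet radius beyond the
#'   pole face, i.e. `2 * magnet$radius`).
#' @param field_stub Optional uniform-gradient stub source,
#'   `list(grad = c(gx, gy, gz), bmag = B0)`, replacing the magnet field
#'   (used for closed-form checks).
#' @param reposition Reposition the magnet against the tube first?
#' @param max_steps Integrator step budget.
#' @return A list with `fate` (`"captured"`, `"exited"` or `"flagged"`),
#'   `t_end`, `end` (final position) and `path` (data frame `t, x, y, z`).
#' @export
integrate_trajectory <- function(cell, inlet, flow, tube,
                                 magnet = magnet_spec(),
                                 fluid = fluid_spec(), rtol = 1e-6,
                                 footprint_radius = NULL, field_stub = NULL,
                                 reposition = TRUE, max_steps = 200000L) {
  stopifnot(inherits(cell, "cell_spec"), length(inlet) == 3L)
  if (sqrt(inlet[2]^2 + inlet[3]^2) > tube$inner_radius)
    stop("inlet position is outside the lumen")
  if (reposition) magnet <- magnet_at_tube(tube, magnet)
  cfg <- .sim_config(flow, tube, magnet, rtol = rtol, atol = 1e-9,
                     max_step_disp = 2.5e-4, max_steps = max_steps,
                     grad_h = 1e-6, footprint_radius = footprint_radius,
                     field_stub = field_stub)
  res <- .trajectory_cpp(as.numeric(inlet), cell$diameter,
                         .saturation_moment(cell$iron_mass),
                         fluid$viscosity,
                         if (cell$moment_model == "langevin") 1L else 0L,
                         .xi_per_tesla(310.15), cfg)
  if (res$fate == 2)
    warning("trajectory did not terminate within the step budget; flagged")
  list(fate = .fate_labels[res$fate + 1], t_end = res$t_end, end = res$end,
       path = as.data.frame(res$path))
}

# flux-weighted inlet sampling over the inlet disc (radius rmax)
.sample_inlet <- function(n, rmax, tube, flow, mode) {
  if (mode == "midplane") {
    if (flow$profile == "plug") {
      y <- runif(n, -rmax, rmax)
    } else {
      # rejection against the parabolic profile along the midplane chord
      y <- numeric(0)
      while (length(y) < n) {
        cand <- runif(2 * n, -rmax, rmax)
        keep <- runif(2 * n) < (1 - (cand / tube$inner_radius)^2)
        y <- c(y, cand[keep])
      }
      y <- y[seq_len(n)]
    }
    return(cbind(0, y, 0))
  }
  if (flow$profile == "plug") {
    rho <- rmax * sqrt(runif(n))
  } else {
    # flux-weighted radial CDF for Poiseuille: F(u) = 2u - u^2, u = (rho/R)^2
    u <- 1 - sqrt(1 - runif(n))
    rho <- rmax * sqrt(u)
  }
  th <- runif(n, 0, 2 * pi)
  cbind(0, rho * sin(th), rho * cos(th))
}

#' Monte-Carlo capture simulation
#'
#' Releases `n` labeled cells at the tube inlet (positions flux-weighted over
#' the inlet disc, diameters and iron loads drawn from the population model),
#' integrates each trajectory through the combined flow and magnetophoretic
#' drift field, and tallies captured (`Q1`) versus escaped (`Q2`) cells into
#' the capture efficiency `CE = 100 Q1 / (Q1 + Q2)` with Monte-Carlo standard
#' error `sqrt(CE (100 - CE) / n)`.
#'
#' @param n Number of cells to simulate (ignored when `inlet` is given).
#' @param flow,tube,fluid Flow, tube and fluid specifications.
#' @param magnet A [magnet_spec()], repositioned against the tube unless
#'   `reposition = FALSE`.
#' @param population A [population_params()] describing the cell size and
#'   iron-load laws; a single [cell_spec()] may be given instead to simulate
#'   identical cells.
#' @param seed RNG seed; a fixed seed makes the result bit-reproducible.
#' @param mode `"3d"` (default) or `"midplane"` (cells confined to the
#'   vertical plane through the magnet axis; cheaper, used by tests).
#' @param moment_model `"saturated"` or `"langevin"` (overrides population
#'   cells).
#' @param inlet Optional explicit `n x 3` inlet positions (bypasses inlet
#'   sampling; population sampling still applies unless a `cell_spec` is
#'   given).
#' @param rtol,max_steps Integrator controls.
#' @param footprint_radius,field_stub See [integrate_trajectory()].
#' @param reposition Reposition the magnet against the tube first?
#' @return An object of class `capture_result`: `Q1`, `Q2`, `flagged`, `n`,
#'   `CE` (percent), `SE` (percent), `seed` and a per-cell `outcomes` data
#'   frame (inlet position, diameter, iron load, fate, end time/position).
#' @examples
#' \donttest{
#' res <- simulate_capture(200, flow_spec(4e-3), tube_geometry(),
#'                         seed = 1, mode = "midplane")
#' res$CE
#' }
#' @export
simulate_capture <- function(n = 2000, flow, tube = tube_geometry(),
                             magnet = magnet_spec(), fluid = fluid_spec(),
                             population = population_params(), seed = NULL,
                             mode = c("3d", "midplane"),
                             moment_model = c("saturated", "langevin"),
                             inlet = NULL, rtol = 1e-6,
                             footprint_radius = NULL, field_stub = NULL,
                             reposition = TRUE, max_steps = 200000L) {
  mode <- match.arg(mode)
  moment_model <- match.arg(moment_model)
  stopifnot(inherits(flow, "flow_spec"), inherits(tube, "tube_geometry"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (reposition) magnet <- magnet_at_tube(tube, magnet)
  if (inherits(population, "cell_spec")) {
    if (is.null(inlet)) {
      stopifnot(n >= 1)
      diam <- rep(population$diameter, n)
      iron <- rep(population$iron_mass, n)
    } else {
      inlet <- .as_points(inlet)
      n <- nrow(inlet)
      diam <- rep(population$diameter, n)
      iron <- rep(population$iron_mass, n)
    }
  } else {
    stopifnot(inherits(population, "population_params"))
    if (!is.null(inlet)) {
      inlet <- .as_points(inlet)
      n <- nrow(inlet)
    }
    stopifnot(n >= 1)
    pop <- sample_cell_population(n, population)
    diam <- pop$diameter_m
    iron <- pop$iron_kg
  }
  if (is.null(inlet)) {
    rmax <- tube$inner_radius - max(diam) / 2
    inlet <- .sample_inlet(n, rmax, tube, flow, mode)
  }
  cfg <- .sim_config(flow, tube, magnet, rtol = rtol, atol = 1e-9,
                     max_step_disp = 2.5e-4, max_steps = max_steps,
                     grad_h = 1e-6, footprint_radius = footprint_radius,
                     field_stub = field_stub)
  res <- .simulate_capture_cpp(inlet, diam, .saturation_moment(iron),
                               fluid$viscosity,
                               if (moment_model == "langevin") 1L else 0L,
                               .xi_per_tesla(310.15), cfg)
  fate <- .fate_labels[res[, 1] + 1]
  Q1 <- sum(fate == "captured")
  Q2 <- sum(fate == "exited")
  flagged <- sum(fate == "flagged")
  CE <- if (Q1 + Q2 > 0) 100 * Q1 / (Q1 + Q2) else NA_real_
  outcomes <- data.frame(cell_id = seq_len(n), diameter_m = diam,
                         iron_kg = iron, inlet_x = inlet[, 1],
                         inlet_y = inlet[, 2], inlet_z = inlet[, 3],
                         fate = fate, t_end = res[, 2], x_end = res[, 3],
                         y_end = res[, 4], z_end = res[, 5])
  structure(list(Q1 = Q1, Q2 = Q2, flagged = flagged, n = n, CE = CE,
                 SE = if (!is.na(CE)) sqrt(CE * (100 - CE) / n) else NA_real_,
                 seed = seed, outcomes = outcomes),
            class = "capture_result")
}

#' @export
print.capture_result <- function(x, ...) {
  cat(sprintf("Capture simulation: n = %d, Q1 = %d captured, Q2 = %d escaped\n",
              x$n, x$Q1, x$Q2))
  cat(sprintf("  CE = %.1f%% (MC SE %.2f%%)", x$CE, x$SE))
  if (x$flagged > 0) cat(sprintf("  [%d flagged]", x$flagged))
  cat("\n")
  invisible(x)
}

#' Capture efficiency from captured and escaped counts
#'
#' `CE = 100 Q1 / (Q1 + Q2)` percent.
#'
#' @param Q1 Captured-cell count.
#' @param Q2 Escaped-cell count.
#' @return CE in percent.
#' @export
capture_efficiency <- function(Q1, Q2) {
  stopifnot(is.numeric(Q1), is.numeric(Q2))
  if (any(Q1 < 0) || any(Q2 < 0)) stop("counts must be non-negative")
  if (any(Q1 + Q2 == 0)) stop("Q1 + Q2 must be positive")
  100 * Q1 / (Q1 + Q2)
}

#' Capture efficiency versus flow velocity
#'
#' Runs [simulate_capture()] at each mean velocity with the same seed (hence
#' the same cell population and inlet draw, giving paired comparisons across
#' velocities).
#'
#' @param velocities Mean velocities in m/s (at least one).
#' @param n Cells per velocity.
#' @param seed RNG seed reused for every velocity.
#' @param ... Passed to [simulate_capture()].
#' @return A data frame with `velocity_m_per_s`, `n`, `Q1`, `Q2`,
#'   `ce_percent`, `se_percent`.
#' @export
ce_velocity_curve <- function(velocities, n = 2000, seed = NULL, ...) {
  stopifnot(is.numeric(velocities), length(velocities) >= 1L,
            all(velocities > 0))
  rows <- lapply(velocities, function(v) {
    res <- simulate_capture(n = n, flow = flow_spec(v), seed = seed, ...)
    data.frame(velocity_m_per_s = v, n = res$n, Q1 = res$Q1, Q2 = res$Q2,
               ce_percent = res$CE, se_percent = res$SE)
  })
  do.call(rbind, rows)
}
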