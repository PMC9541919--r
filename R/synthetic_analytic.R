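#' Analytic velocity fields with closed-form energetics and forces
#'
#' Generates one of four incompressible test fields on a regular grid,
#' together with the closed-form quantities downstream operators must
#' reproduce:
#' \itemize{
#'   \item `uniform`: constant velocity `speed` along `direction`; zero
#'     dissipation, zero pressure gradient, zero hemodynamic force.
#'   \item `rigid_rotation`: solid-body rotation at `omega` rad/s about the
#'     z axis through the grid centre, masked to an inscribed cylinder of
#'     radius `radius`; zero strain rate, hence zero dissipation; kinetic
#'     energy `rho pi h omega^2 R^4 / 4`.
#'   \item `poiseuille`: steady parabolic profile `v_z = v_max (1 - r^2/R^2)`
#'     in a tube of radius `radius` along z; axial pressure gradient
#'     `-4 mu v_max / R^2` and bulk dissipation `2 pi mu v_max^2 L` for a
#'     Newtonian viscosity `mu`.
#'   \item `uniform_acceleration`: spatially uniform ramp
#'     `v = acceleration * t * direction`; pressure-gradient field
#'     `-rho * acceleration * direction` everywhere, so the force on a volume
#'     V is `-rho a V`.
#' }
#'
#' A simple axis-aligned landmark set (apex toward -z) is attached so the
#' anatomical-frame machinery can run on these fields.
#'
#' @param kind one of `"uniform"`, `"rigid_rotation"`, `"poiseuille"`,
#'   `"uniform_acceleration"`.
#' @param dim grid shape (3 integers); `spacing` mm.
#' @param n_frames frame count (>= 3); `rr_interval` s.
#' @param speed m/s (uniform); `direction` unit vector (uniform/acceleration).
#' @param omega rad/s; `v_max` m/s; `radius` mm; `acceleration` m/s2.
#' @param mu Pa s (enters the Poiseuille truth values only).
#' @param density kg/m3 (enters truth values only).
#' @param mask optional logical 3D array overriding the default mask.
#' @param center_offset transverse shift (mm, length 2) of the tube/cylinder
#'   axis relative to the grid centre; convergence of rasterized-boundary
#'   quadrature is assessed in expectation over such sub-voxel placements.
#' @return list with `dataset` (a [flow_dataset()]) and `truth` (closed-form
#'   reference values).
#' @export
make_analytic_field <- function(kind = c("uniform", "rigid_rotation", "poiseuille",
                                         "uniform_acceleration"),
                                dim = c(24, 24, 24), spacing = c(2, 2, 2),
                                n_frames = 4, rr_interval = 1,
                                speed = 0.5, direction = c(1, 0, 0),
                                omega = 10, v_max = 1, radius = 10,
                                acceleration = 1, mu = 0.0035, density = 1025,
                                mask = NULL, center_offset = c(0, 0)) {
  kind <- match.arg(kind)
  dim <- as.integer(dim)
  co <- grid_coords(dim, spacing)
  ctr <- c(max(co$x), max(co$y), max(co$z)) / 2
  ctr[1:2] <- ctr[1:2] + center_offset
  X <- array(rep(co$x - ctr[1], times = dim[2] * dim[3]), dim)
  Y <- array(rep(rep(co$y - ctr[2], each = dim[1]), times = dim[3]), dim)
  frame_times <- (seq_len(n_frames) - 1) * rr_interval / n_frames
  direction <- unitize(direction)

  vel <- array(0, c(dim, 3, n_frames))
  truth <- list(kind = kind, dissipation_w = rep(0, n_frames),
                hdf_n = matrix(0, n_frames, 3), pressure_gradient = c(0, 0, 0))

  if (kind == "uniform") {
    m3 <- mask %||% array(TRUE, dim)
    for (k in seq_len(n_frames)) for (c3 in 1:3) {
      vel[, , , c3, k] <- speed * direction[c3] * m3
    }
  } else if (kind == "rigid_rotation") {
    r2 <- X^2 + Y^2
    m3 <- mask %||% array(r2 <= radius^2, dim)
    vx <- -omega * Y * 1e-3  # mm -> m
    vy <- omega * X * 1e-3
    for (k in seq_len(n_frames)) {
      vel[, , , 1, k] <- vx * m3
      vel[, , , 2, k] <- vy * m3
    }
    height_m <- dim[3] * spacing[3] * 1e-3
    truth$ke_j <- 0.25 * density * pi * height_m * omega^2 * (radius * 1e-3)^4
  } else if (kind == "poiseuille") {
    r2 <- X^2 + Y^2
    m3 <- mask %||% array(r2 <= radius^2, dim)
    vz <- v_max * (1 - r2 / radius^2)
    for (k in seq_len(n_frames)) vel[, , , 3, k] <- vz * m3
    R_m <- radius * 1e-3
    L_m <- dim[3] * spacing[3] * 1e-3
    truth$pressure_gradient <- c(0, 0, -4 * mu * v_max / R_m^2)
    truth$dissipation_w <- rep(2 * pi * mu * v_max^2 * L_m, n_frames)
    truth$hdf_n <- matrix(rep(truth$pressure_gradient * pi * R_m^2 * L_m, each = n_frames),
                          n_frames, 3)
    truth$mu <- mu
  } else {
    m3 <- mask %||% array(TRUE, dim)
    for (k in seq_len(n_frames)) for (c3 in 1:3) {
      vel[, , , c3, k] <- acceleration * frame_times[k] * direction[c3] * m3
    }
    vol_m3 <- sum(m3) * voxel_volume_m3(spacing)
    truth$pressure_gradient <- -density * acceleration * direction
    truth$hdf_n <- matrix(rep(truth$pressure_gradient * vol_m3, each = n_frames), n_frames, 3)
  }

  mask4 <- array(m3, c(dim, n_frames))
  ring <- function(ctr2, r) {
    ang <- seq(0, 2 * pi, length.out = 9)[-9]
    cbind(ctr2[1] + r * cos(ang), ctr2[2] + r * sin(ang), ctr2[3])
  }
  span <- c(max(co$x), max(co$y), max(co$z))
  lm <- landmark_set(
    apex = c(ctr[1], ctr[2], 0),
    mitral_points = ring(c(ctr[1] - 0.15 * span[1], ctr[2], span[3]), 0.2 * span[1]),
    aortic_points = ring(c(ctr[1] + 0.2 * span[1], ctr[2], span[3]), 0.12 * span[1]),
    pm_tips = rbind(c(ctr[1], ctr[2] - 0.2 * span[2], 0.6 * span[3]),
                    c(ctr[1], ctr[2] + 0.2 * span[2], 0.6 * span[3])),
    pm_bases = rbind(c(ctr[1], ctr[2] - 0.2 * span[2], 0.35 * span[3]),
                     c(ctr[1], ctr[2] + 0.2 * span[2], 0.35 * span[3]))
  )
  ds <- flow_dataset(vel, mask4, spacing, frame_times, rr_interval,
                     hematocrit = 0.45, landmarks = lm)
  truth$volume_curve <- rep(sum(m3) * voxel_volume_ml(spacing), n_frames)
  list(dataset = ds, truth = truth)
}
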