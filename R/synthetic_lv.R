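# Contracting half-ellipsoid LV phantom with prescribed volumetrics,
# biphasic (E/A) diastolic filling, landmark tracks and known ground truth.

# Analytic volume model over one cycle starting at end-diastole.
# Returns closed-form V(t) and dV/dt (mL, mL/s) plus the timing constants.
volume_model <- function(edv, ef, rr, systole_fraction, e_to_a_ratio,
                         e_duration_frac, a_duration_frac) {
  sv <- edv * ef
  esv <- edv - sv
  ts <- systole_fraction * rr
  td <- rr - ts
  merged <- !is.finite(e_to_a_ratio)
  if (!merged && e_to_a_ratio <= 0) stop("e_to_a_ratio must be positive")
  if (e_duration_frac + a_duration_frac > 1) stop("E and A waves overlap")
  de <- e_duration_frac * td
  da <- a_duration_frac * td
  if (merged) {
    p_e <- sv * pi / (2 * td); p_a <- 0; de <- td; da <- 0
    v_e <- sv; v_a <- 0
  } else {
    p_a <- sv * pi / 2 / (e_to_a_ratio * de + da)
    p_e <- e_to_a_ratio * p_a
    v_e <- 2 * de * p_e / pi
    v_a <- 2 * da * p_a / pi
  }
  dvdt <- function(t) {
    t <- t %% rr
    out <- numeric(length(t))
    s <- t <= ts
    out[s] <- -sv * pi / (2 * ts) * sin(pi * t[s] / ts)
    e <- t > ts & t <= ts + de
    out[e] <- p_e * sin(pi * (t[e] - ts) / de)
    if (!merged) {
      a <- t > rr - da
      out[a] <- p_a * sin(pi * (t[a] - (rr - da)) / da)
    }
    out
  }
  vol <- function(t) {
    t <- t %% rr
    out <- numeric(length(t))
    s <- t <= ts
    out[s] <- edv - sv * (1 - cos(pi * t[s] / ts)) / 2
    e <- t > ts & t <= ts + de
    out[e] <- esv + v_e * (1 - cos(pi * (t[e] - ts) / de)) / 2
    d <- t > ts + de & t <= rr - da
    out[d] <- esv + v_e
    if (!merged) {
      a <- t > rr - da
      out[a] <- esv + v_e + v_a * (1 - cos(pi * (t[a] - (rr - da)) / da)) / 2
    }
    out
  }
  list(vol = vol, dvdt = dvdt, sv = sv, esv = esv, ts = ts, td = td,
       de = de, da = da, p_e = p_e, p_a = p_a, merged = merged,
       e_peak_time = ts + de / 2,
       a_peak_time = if (merged) NA_real_ else rr - da / 2)
}

#' Contracting-ellipsoid left-ventricle phantom
#'
#' Builds a time-resolved half-ellipsoid chamber (apex fixed, base plane
#' fixed, short axis contracting) whose volume follows a prescribed curve:
#' half-cosine systolic ejection over `systole_fraction` of the cycle, then
#' biphasic diastolic filling with E- and A-wave half-sine flow humps whose
#' peak-flow ratio is `e_to_a_ratio` (`Inf` gives a merged single-peak
#' inflow). The interior velocity is a smooth, divergence-free jet model
#' constructed from a Stokes streamfunction about the active-orifice axis
#' (aortic during ejection, mitral during filling): a flat-top jet whose
#' slice flux equals the rate of change of the cavity volume beyond each
#' short-axis plane, fed by the streamfunction's radial far field, which at
#' the wall reproduces the mean wall-following motion. The jet axis bends
#' smoothly from the orifice centre onto the chamber's long axis with depth.
#' Being divergence-free, the field transports Lagrangian volume
#' consistently, so pathline bookkeeping (direct flow + delayed ejection
#' equals the ejected volume) holds by construction. The model's contract is
#' flux consistency, smoothness and incompressibility, not a Navier-Stokes
#' solution.
#'
#' Landmarks are emitted per frame: fixed apex, mitral and aortic annulus
#' rings on the base plane (tracking the wall scale), and papillary-muscle
#' tips/bases at fixed long-axis fractions (defaults 0.40 and 0.65 of the
#' base-apex distance).
#'
#' @param edv end-diastolic volume, mL; `ef` ejection fraction in (0, 1).
#' @param heart_rate bpm.
#' @param systole_fraction fraction of the cycle spent ejecting.
#' @param e_to_a_ratio prescribed E/A peak-flow ratio (`Inf` = merged inflow).
#' @param e_duration_frac,a_duration_frac E-/A-wave durations as fractions of
#'   diastole.
#' @param dim,spacing grid shape and voxel size (mm).
#' @param n_frames reconstructed frames per cycle.
#' @param transverse_flow peak amplitude (m/s) of a transverse sloshing
#'   component (parabolic envelope, zero at the wall) emulating disorganized
#'   intracavitary flow (0 = axisymmetric phantom).
#' @param noise_sd additive Gaussian velocity noise per component, m/s.
#' @param seed RNG seed for the noise.
#' @param hematocrit stored in the dataset.
#' @param long_axis_direction world direction of the base-to-apex axis; the
#'   phantom is built apex-down and rotated with [rotate_dataset()] when this
#'   is not `c(0, 0, -1)`.
#' @param pm_tip_frac,pm_base_frac long-axis fractions of the PM planes.
#' @return list with `dataset` and `truth` (volume curve, transvalvular flows,
#'   SV/EF, phase timing, geometry constants).
#' @export
make_ellipsoid_lv <- function(edv = 150, ef = 0.60, heart_rate = 70,
                              systole_fraction = 0.35, e_to_a_ratio = 2,
                              e_duration_frac = 0.45, a_duration_frac = 0.35,
                              dim = c(32, 32, 48), spacing = c(2.5, 2.5, 2.5),
                              n_frames = 30, transverse_flow = 0,
                              noise_sd = 0, seed = 1, hematocrit = 0.42,
                              long_axis_direction = c(0, 0, -1),
                              pm_tip_frac = 0.40, pm_base_frac = 0.65) {
  if (edv <= 0) stop("edv must be positive")
  if (ef <= 0 || ef >= 1) stop("ef must be in (0, 1)")
  if (systole_fraction <= 0 || systole_fraction >= 1) stop("systole_fraction must be in (0, 1)")
  dim <- as.integer(dim)
  rr <- 60 / heart_rate
  vm <- volume_model(edv, ef, rr, systole_fraction, e_to_a_ratio,
                     e_duration_frac, a_duration_frac)
  co <- grid_coords(dim, spacing)
  ext <- c(max(co$x), max(co$y), max(co$z))
  xc <- ext[1] / 2; yc <- ext[2] / 2
  z_b <- ext[3] - 5 * spacing[3]           # base plane, margin above
  c_ax <- 0.72 * ext[3]                    # long semi-axis (apex depth)
  if (z_b - c_ax < spacing[3]) stop("phantom long axis does not fit the grid")
  a0 <- sqrt(3 * edv * 1000 / (2 * pi * c_ax))
  if (a0 > min(xc, yc) - 1.5 * max(spacing)) {
    stop("phantom does not fit the grid transversely; enlarge the grid or lower edv")
  }
  # orifice layout (end-diastolic, scaled with the wall); the jet occupies
  # 75% of the annulus radius, a vena-contracta-like margin that also keeps
  # the trilinearly smeared jet inside the annulus disc at clinical voxel
  # sizes so measured transvalvular flux stays consistent
  e_mi0 <- 0.40 * a0; r_mi0 <- 0.40 * a0   # mitral: -x side
  e_ao0 <- 0.42 * a0; r_ao0 <- 0.34 * a0   # aortic: +x side
  jet_frac <- 0.75
  z_d <- spacing[3] * floor(z_b / spacing[3])  # annulus plane: top voxel-centre plane
  z_col <- z_b - 0.25 * c_ax               # start of the orifice funnel

  frame_times <- (seq_len(n_frames) - 1) * rr / n_frames
  X <- array(rep(co$x - xc, times = dim[2] * dim[3]), dim)
  Y <- array(rep(rep(co$y - yc, each = dim[1]), times = dim[3]), dim)
  zv <- co$z                               # 1D z grid
  uv <- pmin(pmax((z_b - zv) / c_ax, 0), 1)
  w_shape <- c_ax * (2 / 3 - uv + uv^3 / 3)  # W(z) / (pi a^2), mm
  a_shape <- pmax(1 - uv^2, 0)               # A(z) / (pi a^2)
  # jet-axis bend: 1 at the annulus plane, 0 from mid-cavity down
  gam <- pmin(pmax((zv - (z_b - 0.45 * c_ax)) / (z_d - (z_b - 0.45 * c_ax)), 0), 1)
  gam <- gam^2 * (3 - 2 * gam)
  to3d <- function(v1d) array(rep(v1d, each = dim[1] * dim[2]), dim)

  set.seed(seed)
  phi0 <- pi / 5
  vel <- array(0, c(dim, 3, n_frames))
  mask <- array(FALSE, c(dim, n_frames))
  lms <- vector("list", n_frames)
  Z <- to3d(zv)
  for (k in seq_len(n_frames)) {
    t <- frame_times[k]
    V <- vm$vol(t); dV <- vm$dvdt(t)
    s <- sqrt(V / edv)
    a_t <- a0 * s
    c0 <- -dV / V                          # uniform wall-divergence rate, 1/s
    m3 <- (X^2 + Y^2) / a_t^2 + ((Z - z_b) / c_ax)^2 <= 1 & Z <= z_b
    # Stokes-streamfunction jet about the active orifice axis.
    # Slice flux (upward, mm^3/s): F(z) = c0 * W(z); its z-derivative c0 * A(z).
    Fz <- c0 * pi * a_t^2 * w_shape
    dFz <- c0 * pi * a_t^2 * a_shape
    e_act <- if (dV < 0) e_ao0 * s else -e_mi0 * s
    r_jet <- jet_frac * (if (dV < 0) r_ao0 else r_mi0) * s
    # jet radius: widens with depth, capped below the wall distance
    d_wall <- pmax(a_t * sqrt(a_shape) - abs(e_act) * gam, 0)
    Rz <- pmin(r_jet + 0.30 * (z_d - zv), 0.8 * d_wall)
    Rz <- pmax(Rz, 0.25 * min(spacing))
    dRz <- c(0, diff(Rz)) / c(1, diff(zv))  # dR/dz on the z grid
    ax_x <- xc + e_act * gam                # bent jet axis (x only)
    dax <- c(0, diff(ax_x)) / c(1, diff(zv))
    XA <- X - to3d(ax_x - xc)
    rho2 <- XA^2 + Y^2
    rho <- sqrt(rho2)
    xi <- rho / to3d(Rz)
    inj <- xi < 1
    # flat-top profile: G(xi) = (4/3)(xi^2 - xi^8/4), G'(xi) = (8/3) xi (1 - xi^6)
    G <- ifelse(inj, (4 / 3) * (xi^2 - xi^8 / 4), 1)
    Gp <- ifelse(inj, (8 / 3) * xi * (1 - xi^6), 0)
    F3 <- to3d(Fz); dF3 <- to3d(dFz); R3 <- to3d(Rz); dR3 <- to3d(dRz)
    vz <- F3 / (2 * pi * R3^2) * ifelse(inj, (8 / 3) * (1 - xi^6), 0)
    G_over_rho <- ifelse(rho > 1e-9, G / rho, 0)
    vrho <- -dF3 / (2 * pi) * G_over_rho + F3 * dR3 / (2 * pi * R3^2) * Gp
    ex <- ifelse(rho > 1e-9, XA / rho, 0)
    ey <- ifelse(rho > 1e-9, Y / rho, 0)
    vx <- vrho * ex + vz * to3d(dax)       # bent-axis following term
    vy <- vrho * ey
    vx <- vx * 1e-3; vy <- vy * 1e-3; vz <- vz * 1e-3  # mm/s -> m/s
    if (transverse_flow > 0) {
      # transverse sloshing with a parabolic envelope vanishing at the wall:
      # carries net transverse momentum (disorganized-flow surrogate) without
      # pushing near-wall fluid through the static wall
      sl <- transverse_flow * sin(2 * pi * t / rr) * pmax(0, 1 - (X^2 + Y^2) / a_t^2)
      vx <- vx + sl * cos(phi0)
      vy <- vy + sl * sin(phi0)
    }
    vx[!m3] <- 0; vy[!m3] <- 0; vz[!m3] <- 0
    if (noise_sd > 0) {
      nin <- sum(m3)
      vx[m3] <- vx[m3] + stats::rnorm(nin, sd = noise_sd)
      vy[m3] <- vy[m3] + stats::rnorm(nin, sd = noise_sd)
      vz[m3] <- vz[m3] + stats::rnorm(nin, sd = noise_sd)
    }
    vel[, , , 1, k] <- vx; vel[, , , 2, k] <- vy; vel[, , , 3, k] <- vz
    mask[, , , k] <- m3

    ring <- function(cx, r) {
      ang <- seq(0, 2 * pi, length.out = 9)[-9]
      cbind(cx + r * cos(ang), yc + r * sin(ang), z_d)
    }
    a_tip <- a_t * sqrt(1 - pm_tip_frac^2)
    a_bas <- a_t * sqrt(1 - pm_base_frac^2)
    lms[[k]] <- landmark_set(
      apex = c(xc, yc, z_b - c_ax),
      mitral_points = ring(xc - e_mi0 * s, r_mi0 * s),
      aortic_points = ring(xc + e_ao0 * s, r_ao0 * s),
      pm_tips = rbind(c(xc, yc - 0.6 * a_tip, z_b - pm_tip_frac * c_ax),
                      c(xc, yc + 0.6 * a_tip, z_b - pm_tip_frac * c_ax)),
      pm_bases = rbind(c(xc, yc - 0.6 * a_bas, z_b - pm_base_frac * c_ax),
                       c(xc, yc + 0.6 * a_bas, z_b - pm_base_frac * c_ax))
    )
  }

  ds <- flow_dataset(vel, mask, spacing, frame_times, rr,
                     hematocrit = hematocrit, landmarks = lms)
  canonical <- c(0, 0, -1)
  lad <- unitize(long_axis_direction)
  if (max(abs(lad - canonical)) > 1e-12) {
    v <- c(canonical[2] * lad[3] - canonical[3] * lad[2],
           canonical[3] * lad[1] - canonical[1] * lad[3],
           canonical[1] * lad[2] - canonical[2] * lad[1])
    cth <- sum(canonical * lad)
    if (sqrt(sum(v^2)) < 1e-12) {
      R <- if (cth > 0) diag(3) else diag(c(1, -1, -1))
    } else {
      vx_m <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
      R <- diag(3) + vx_m + vx_m %*% vx_m / (1 + cth)
    }
    ds <- rotate_dataset(ds, R)
  }

  dv_frames <- vm$dvdt(frame_times)
  truth <- list(
    volume_curve = vm$vol(frame_times),
    aortic_flow = pmax(-dv_frames, 0),
    mitral_flow = pmax(dv_frames, 0),
    sv = vm$sv, esv = vm$esv, edv = edv, ef = ef,
    inflow_volume = vm$sv,
    avc_time = vm$ts, e_peak_time = vm$e_peak_time, a_peak_time = vm$a_peak_time,
    e_a_peak_ratio = if (vm$merged) NA_real_ else vm$p_e / vm$p_a,
    merged_inflow = vm$merged,
    rr_interval = rr,
    geometry = list(a0 = a0, c_ax = c_ax, z_base = z_b, z_annulus = z_d,
                    apex = c(xc, yc, z_b - c_ax),
                    pm_tip_frac = pm_tip_frac, pm_base_frac = pm_base_frac),
    vol_fun = vm$vol, dvdt_fun = vm$dvdt
  )
  list(dataset = ds, truth = truth)
}
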