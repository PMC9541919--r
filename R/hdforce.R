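#' Pressure-gradient field from the Navier-Stokes momentum balance
#'
#' Per in-mask voxel,
#' \deqn{b = -\rho(\partial v/\partial t + (v\cdot\nabla)v) + \nabla\cdot(2\mu S),}
#' in Pa/m. The temporal derivative is a cyclic three-point difference on the
#' frame times (the last frame wraps to the first, consistent with
#' retrospective gating), gated on mask membership at the neighbouring frames
#' (one-sided in time where a voxel leaves the mask). Spatial terms use the
#' masked finite-difference operator of [velocity_gradient()]. The viscous
#' term is the full variable-viscosity divergence `div(2 mu S)`, which reduces
#' to `mu laplacian(v)` for uniform viscosity; it can be dropped with
#' `include_viscous = FALSE` to mimic inertia-only implementations.
#'
#' @param ds a [flow_dataset()] with at least 3 frames.
#' @param frame frame index.
#' @param params a [rheology_params()].
#' @param include_viscous include the viscous stress divergence.
#' @param grad optional precomputed [velocity_gradient()] for the frame.
#' @return list with `b`, a 4D array `[nx, ny, nz, 3]` of world-frame
#'   components (Pa/m, zero outside the mask), and `mask`.
#' @export
pressure_gradient_field <- function(ds, frame, params = rheology_params(),
                                    include_viscous = TRUE, grad = NULL) {
  nt <- dim(ds$mask)[4]
  if (nt < 3) stop("temporal derivative needs at least 3 frames")
  g <- as_grid_frame(ds)
  d3 <- dim(g$mask)[1:3]
  k <- frame
  kp <- if (k == nt) 1 else k + 1
  km <- if (k == 1) nt else k - 1
  t0 <- g$frame_times[k]
  tp <- if (k == nt) g$frame_times[1] + g$rr_interval else g$frame_times[kp]
  tm <- if (k == 1) g$frame_times[nt] - g$rr_interval else g$frame_times[km]
  h1 <- t0 - tm; h2 <- tp - t0
  m0 <- g$mask[, , , k]; mp <- g$mask[, , , kp]; mm <- g$mask[, , , km]
  cen <- m0 & mp & mm
  fwd <- m0 & mp & !mm
  bwd <- m0 & mm & !mp

  if (is.null(grad)) grad <- velocity_gradient(g, k)
  ss <- strain_double_dot(grad$g)
  mu <- viscosity(sqrt(2 * ss), g$hematocrit, params)
  rho <- params$density

  b <- array(0, c(d3, 3))
  for (i in 1:3) {
    f0 <- g$velocity[, , , i, k]
    fp <- g$velocity[, , , i, kp]
    fm <- g$velocity[, , , i, km]
    dvdt <- array(0, d3)
    dvdt[cen] <- (h1^2 * fp[cen] - h2^2 * fm[cen] + (h2^2 - h1^2) * f0[cen]) /
      (h1 * h2 * (h1 + h2))
    dvdt[fwd] <- (fp[fwd] - f0[fwd]) / h2
    dvdt[bwd] <- (f0[bwd] - fm[bwd]) / h1

    conv <- array(0, d3)
    for (j in 1:3) conv <- conv + g$velocity[, , , j, k] * grad$g[, , , i, j]

    bi <- -rho * (dvdt + conv)
    if (include_viscous) {
      for (j in 1:3) {
        t_ij <- mu * (grad$g[, , , i, j] + grad$g[, , , j, i])  # 2 mu S_ij
        bi <- bi + apply_deriv(t_ij, grad$plans[[j]], g$spacing[j])
      }
    }
    bi[!m0] <- 0
    b[, , , i] <- bi
  }
  # map components back to world coordinates
  Q <- ds$orientation
  if (max(abs(Q - diag(3))) > 0) {
    bm <- matrix(b, ncol = 3) %*% t(Q)
    b <- array(bm, c(d3, 3))
  }
  list(b = b, mask = m0)
}

#' Hemodynamic force of one frame
#'
#' The volume integral of the pressure-gradient field `b` over the chamber,
#' projected onto the anatomical triad. Positive basal-apical points from base
#' to apex, positive septal-lateral toward the lateral wall and positive
#' inferior-anterior toward the anterior wall. With
#' `convention = "wall_on_blood"` the global sign is flipped (the
#' action-reaction reading of the same vector).
#'
#' @param bfield result of [pressure_gradient_field()].
#' @param spacing voxel spacing, mm.
#' @param frame an `anatomical_frame` from [build_frame()].
#' @param volume_ml current LV volume, mL, for normalization.
#' @param convention `"pressure_gradient"` (default) or `"wall_on_blood"`.
#' @return named list: `vector` (N, world), `components` (N, triad),
#'   `components_v` (N/L, triad).
#' @export
hemodynamic_force <- function(bfield, spacing, frame, volume_ml,
                              convention = c("pressure_gradient", "wall_on_blood")) {
  convention <- match.arg(convention)
  vv <- voxel_volume_m3(spacing)
  hdf <- vapply(1:3, function(i) sum(bfield$b[, , , i][bfield$mask]) * vv, numeric(1))
  if (convention == "wall_on_blood") hdf <- -hdf
  comp <- c(
    basal_apical = sum(hdf * frame$basal_apical),
    septal_lateral = sum(hdf * frame$septal_lateral),
    inferior_anterior = sum(hdf * frame$inferior_anterior)
  )
  list(vector = hdf, components = comp, components_v = comp / (volume_ml / 1000))
}

#' Hemodynamic-force time series
#'
#' Runs [pressure_gradient_field()] and [hemodynamic_force()] for every frame.
#'
#' @param ds a [flow_dataset()] with landmarks.
#' @param params a [rheology_params()].
#' @param volumes optional volume curve (mL); computed from the mask if absent.
#' @param include_viscous passed through.
#' @param convention passed through.
#' @return object of class `hdf_series`: data.frame `samples` with time, world
#'   vector, triad components (N) and volume-normalized components (N/L).
#' @export
compute_hdf_series <- function(ds, params = rheology_params(), volumes = NULL,
                               include_viscous = TRUE,
                               convention = "pressure_gradient") {
  nt <- dim(ds$mask)[4]
  if (is.null(volumes)) volumes <- lv_volume_series(ds)$volume_ml
  rows <- vector("list", nt)
  for (k in seq_len(nt)) {
    bf <- pressure_gradient_field(ds, k, params, include_viscous = include_viscous)
    fr <- build_frame(ds$landmarks[[k]])
    h <- hemodynamic_force(bf, ds$spacing, fr, volumes[k], convention = convention)
    rows[[k]] <- data.frame(
      frame = k, time = ds$frame_times[k],
      fx = h$vector[1], fy = h$vector[2], fz = h$vector[3],
      basal_apical = h$components[["basal_apical"]],
      septal_lateral = h$components[["septal_lateral"]],
      inferior_anterior = h$components[["inferior_anterior"]],
      basal_apical_v = h$components_v[["basal_apical"]],
      septal_lateral_v = h$components_v[["septal_lateral"]],
      inferior_anterior_v = h$components_v[["inferior_anterior"]],
      volume_ml = volumes[k]
    )
  }
  structure(list(samples = do.call(rbind, rows),
                 frame_times = ds$frame_times, rr_interval = ds$rr_interval),
            class = "hdf_series")
}

#' RMS summaries, R_RMS and peak table of a hemodynamic-force series
#'
#' Time-weighted RMS of each volume-normalized component over the whole cycle
#' and per phase. `R_RMS` per phase is the RMS of the transversal force
#' (root of the summed squared septal-lateral and inferior-anterior RMS
#' values) divided by the basal-apical RMS of the same phase. The peak table
#' holds, for each component and window (systole, E-wave, A-wave), the
#' signed value of largest magnitude.
#'
#' @param series a [compute_hdf_series()] result.
#' @param phases a [detect_phases()] result.
#' @return list: `rms` (N/L; rows cycle/systole/diastole), `r_rms`
#'   (systole, diastole), `peaks` data.frame.
#' @export
summarize_hdf <- function(series, phases) {
  s <- series$samples
  tt <- series$frame_times; rr <- series$rr_interval
  comps <- c("basal_apical_v", "septal_lateral_v", "inferior_anterior_v")
  wins <- list(cycle = c(0, rr), systole = phases$systole, diastole = phases$diastole)
  rms <- sapply(comps, function(cn) {
    vapply(wins, function(w) cyclic_rms(tt, s[[cn]], rr, w[1], w[2]), numeric(1))
  })
  rownames(rms) <- names(wins)
  r_rms <- vapply(c("systole", "diastole"), function(ph) {
    ba <- rms[ph, "basal_apical_v"]
    if (ba < 1e-12) stop("R_RMS undefined: basal-apical RMS is zero in ", ph)
    sqrt(rms[ph, "septal_lateral_v"]^2 + rms[ph, "inferior_anterior_v"]^2) / ba
  }, numeric(1))

  pk_win <- list(systolic = phases$systole, e_wave = phases$e_wave_window,
                 a_wave = phases$a_wave_window)
  peaks <- do.call(rbind, lapply(names(pk_win), function(nm) {
    if (is.null(pk_win[[nm]])) return(NULL)
    do.call(rbind, lapply(comps, function(cn) {
      # signed extremum: peak of |x| within the window
      pa <- window_peak(tt, abs(s[[cn]]), pk_win[[nm]], rr)
      sgn <- sign(cyclic_interp(tt, s[[cn]], rr, pa[["time"]]))
      data.frame(window = nm, component = sub("_v$", "", cn),
                 value = sgn * pa[["value"]], time = pa[["time"]])
    }))
  }))
  list(rms = rms, r_rms = r_rms, peaks = peaks)
}

#' Early-diastolic filling impulse
#'
#' The time integral of the volume-normalized basal-apical force from aortic
#' valve closure to its next zero crossing (both endpoints sub-frame, by
#' linear interpolation), in Ns/L. When the component has no zero crossing
#' within diastole the impulse is undefined and returned as `NA` with a
#' `defined = FALSE` flag.
#'
#' @param series a [compute_hdf_series()] result.
#' @param phases a [detect_phases()] result.
#' @return list: `impulse` (signed, Ns/L), `magnitude`, `t_start`, `t_end`,
#'   `defined`.
#' @export
filling_impulse <- function(series, phases) {
  s <- series$samples
  tt <- series$frame_times; rr <- series$rr_interval
  avc <- phases$aortic_valve_closure
  # dense piecewise-linear scan of the BA component over diastole
  grid <- sort(unique(c(avc, tt[tt > avc], rr)))
  vals <- cyclic_interp(tt, s$basal_apical_v, rr, pmin(grid, rr - 1e-12))
  t_end <- NA_real_
  for (k in seq_len(length(grid) - 1)) {
    v0 <- vals[k]; v1 <- vals[k + 1]
    if (abs(v0) < 1e-15 && k == 1) next
    if (v0 != 0 && (sign(v0) != sign(v1))) {
      t_end <- grid[k] + abs(v0) / (abs(v0) + abs(v1)) * (grid[k + 1] - grid[k])
      break
    }
    if (v1 == 0) { t_end <- grid[k + 1]; break }
  }
  if (is.na(t_end) || max(abs(vals)) < 1e-15) {
    return(list(impulse = NA_real_, magnitude = NA_real_, t_start = avc,
                t_end = NA_real_, defined = FALSE))
  }
  imp <- cyclic_integral(tt, s$basal_apical_v, rr, avc, t_end)
  list(impulse = imp, magnitude = abs(imp), t_start = avc, t_end = t_end,
       defined = TRUE)
}
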