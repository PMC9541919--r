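#' Kinetic energy of one frame
#'
#' The sum over in-mask voxels of `1/2 m |v|^2`, with `m` the blood mass in
#' one voxel (`density * voxel volume`). Regional sums are returned when a
#' label field is supplied.
#'
#' @param ds a [flow_dataset()].
#' @param frame frame index.
#' @param density blood density, kg/m3.
#' @param labels optional [subdivide_regions()] result.
#' @return named numeric: `global` (J) and, with labels, `basal`, `mid`,
#'   `apical`.
#' @export
kinetic_energy <- function(ds, frame = 1, density = 1025, labels = NULL) {
  m <- ds$mask[, , , frame]
  v2 <- ds$velocity[, , , 1, frame]^2 + ds$velocity[, , , 2, frame]^2 +
    ds$velocity[, , , 3, frame]^2
  ke_vox <- 0.5 * density * voxel_volume_m3(ds$spacing) * v2
  out <- c(global = sum(ke_vox[m]))
  if (!is.null(labels)) {
    lab <- labels$labels[, , , frame]
    for (r in 1:3) out[c("basal", "mid", "apical")[r]] <- sum(ke_vox[m & lab == r])
  }
  out
}

#' Viscous energy-loss rate of one frame
#'
#' Bulk viscous dissipation: the volume integral of `Phi = 2 mu (S:S)` over
#' the mask, with `S` the strain-rate tensor. Near-wall boundary-layer losses
#' outside the voxel grid are not represented.
#'
#' @param ds a [flow_dataset()].
#' @param frame frame index.
#' @param params a [rheology_params()]; the viscosity field is derived from
#'   the frame's shear rate and the dataset haematocrit.
#' @param labels optional region labels.
#' @param grad optionally, a precomputed [velocity_gradient()] for the frame.
#' @return named numeric: `global` dissipation rate (W) and regional rates.
#' @export
viscous_loss_rate <- function(ds, frame = 1, params = rheology_params(),
                              labels = NULL, grad = NULL) {
  if (is.null(grad)) grad <- velocity_gradient(ds, frame)
  ss <- strain_double_dot(grad$g)
  mu <- viscosity(sqrt(2 * ss), ds$hematocrit, params)
  phi <- 2 * mu * ss  # W/m^3
  m <- grad$mask
  vv <- voxel_volume_m3(ds$spacing)
  out <- c(global = sum(phi[m]) * vv)
  if (!is.null(labels)) {
    lab <- labels$labels[, , , frame]
    for (r in 1:3) out[c("basal", "mid", "apical")[r]] <- sum(phi[m & lab == r]) * vv
  }
  out
}

# locate the peak of a sampled cyclic curve within a time window; optional
# 3-point parabolic refinement of the peak position/value.
window_peak <- function(times, values, window, rr, refine = FALSE) {
  tt <- c(times, times[1] + rr)
  vv <- c(values, values[1])
  inw <- which(tt >= window[1] - 1e-12 & tt <= window[2] + 1e-12)
  if (!length(inw)) return(c(value = NA_real_, time = NA_real_))
  k <- inw[which.max(vv[inw])]
  val <- vv[k]; tim <- tt[k]
  if (refine && k > 1 && k < length(vv)) {
    y1 <- vv[k - 1]; y2 <- vv[k]; y3 <- vv[k + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-12) {
      delta <- 0.5 * (y1 - y3) / den
      if (abs(delta) <= 1) {
        tim <- tim + delta * (tt[k + 1] - tt[k])
        val <- y2 - 0.25 * (y1 - y3) * delta
      }
    }
  }
  c(value = val, time = tim %% rr)
}

#' Volume-normalized energetics with phase aggregates and peaks
#'
#' Normalizes kinetic energy to the instantaneous chamber (or regional)
#' volume, integrates the viscous loss rate over each phase, and extracts the
#' systolic, E-wave and (when present) A-wave KE_V peaks. EL per phase is
#' normalized to the phase-mean volume by default
#' (`normalization = "phase_mean_volume"`); a per-frame-normalized,
#' then-integrated variant is available (`"per_frame"`).
#'
#' @param ke matrix of KE per frame (rows) by region column (`global` first),
#'   J; a plain vector is treated as global-only.
#' @param el_rate matching dissipation-rate matrix, W.
#' @param volumes matching volume matrix, mL (columns aligned with `ke`).
#' @param phases a [detect_phases()] result.
#' @param frame_times s; `rr_interval` s.
#' @param normalization see above.
#' @param refine_peaks 3-point parabolic peak refinement.
#' @return object of class `energetics_series`: per-frame `ke_v` (J/L),
#'   `el_rate` (W), phase tables `el_v` (J/L) and `ke_v_phase_mean` (J/L), and
#'   a `peaks` table.
#' @export
normalize_and_summarize <- function(ke, el_rate, volumes, phases, frame_times,
                                    rr_interval,
                                    normalization = c("phase_mean_volume", "per_frame"),
                                    refine_peaks = FALSE) {
  normalization <- match.arg(normalization)
  ke <- cbind(ke); el_rate <- cbind(el_rate); volumes <- cbind(volumes)
  std <- c("global", "basal", "mid", "apical")
  if (is.null(colnames(ke)) || !all(colnames(ke) %in% std)) {
    colnames(ke) <- std[seq_len(ncol(ke))]
  }
  colnames(el_rate) <- colnames(ke); colnames(volumes) <- colnames(ke)
  if (any(volumes <= 0)) stop("zero or negative volume: cannot normalize")
  ke_v <- ke / (volumes / 1000)          # J / L
  el_rate_v <- el_rate / (volumes / 1000)  # W / L

  win <- list(systole = phases$systole, diastole = phases$diastole,
              e_wave = phases$e_wave_window, a_wave = phases$a_wave_window)
  regions <- colnames(ke)
  el_v <- ke_mean <- matrix(NA_real_, length(win), length(regions),
                            dimnames = list(names(win), regions))
  for (w in seq_along(win)) {
    if (is.null(win[[w]])) next
    t0 <- win[[w]][1]; t1 <- win[[w]][2]
    for (r in seq_along(regions)) {
      if (normalization == "phase_mean_volume") {
        el_int <- cyclic_integral(frame_times, el_rate[, r], rr_interval, t0, t1)
        vbar <- cyclic_mean(frame_times, volumes[, r], rr_interval, t0, t1) / 1000
        el_v[w, r] <- el_int / vbar
      } else {
        el_v[w, r] <- cyclic_integral(frame_times, el_rate_v[, r], rr_interval, t0, t1)
      }
      ke_mean[w, r] <- cyclic_mean(frame_times, ke_v[, r], rr_interval, t0, t1)
    }
  }

  pk_win <- list(systolic = phases$systole, e_wave = phases$e_wave_window,
                 a_wave = phases$a_wave_window)
  peaks <- do.call(rbind, lapply(names(pk_win), function(nm) {
    if (is.null(pk_win[[nm]])) return(NULL)
    do.call(rbind, lapply(regions, function(r) {
      p <- window_peak(frame_times, ke_v[, r], pk_win[[nm]], rr_interval, refine = refine_peaks)
      data.frame(peak = nm, region = r, ke_v = p[["value"]], time = p[["time"]])
    }))
  }))

  structure(list(ke = ke, ke_v = ke_v, el_rate = el_rate,
                 el_v = el_v, ke_v_phase_mean = ke_mean, peaks = peaks,
                 frame_times = frame_times, rr_interval = rr_interval,
                 normalization = normalization),
            class = "energetics_series")
}

#' @export
print.energetics_series <- function(x, ...) {
  cat("<energetics_series>\n")
  cat(sprintf("  systolic global KE_V peak: %.4g J/L\n",
              x$peaks$ke_v[x$peaks$peak == "systolic" & x$peaks$region == "global"]))
  cat(sprintf("  EL_V (systole, global): %.4g J/L\n", x$el_v["systole", "global"]))
  invisible(x)
}
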