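#' LV volume per frame
#'
#' Volume is voxel count times voxel volume. When a `region_labels` object is
#' supplied, per-region volumes (basal/mid/apical) are returned as well.
#'
#' @param mask 4D logical array `[nx, ny, nz, nt]` (or a `flow_dataset`).
#' @param spacing voxel edge lengths, mm (ignored when `mask` is a dataset).
#' @param labels optional [subdivide_regions()] result.
#' @return data.frame with columns `frame`, `volume_ml` and, with labels,
#'   `basal_ml`, `mid_ml`, `apical_ml`.
#' @export
lv_volume_series <- function(mask, spacing = NULL, labels = NULL) {
  if (inherits(mask, "flow_dataset")) {
    spacing <- mask$spacing
    mask <- mask$mask
  }
  nt <- dim(mask)[4]
  vv <- voxel_volume_ml(spacing)
  out <- data.frame(frame = seq_len(nt),
                    volume_ml = vapply(seq_len(nt), function(k) {
                      n <- sum(mask[, , , k])
                      if (n == 0) stop(sprintf("mask is empty at frame %d", k))
                      n * vv
                    }, numeric(1)))
  if (!is.null(labels)) {
    for (rg in c("basal", "mid", "apical")) {
      out[[paste0(rg, "_ml")]] <- vapply(seq_len(nt), function(k) {
        sum(labels$labels[, , , k] == match(rg, c("basal", "mid", "apical"))) * vv
      }, numeric(1))
    }
  }
  out
}

#' Anatomical reference frame from landmarks
#'
#' Builds the right-handed orthonormal triad used to project hemodynamic
#' forces: `basal_apical` is the unit vector from the mitral-annulus centroid
#' to the apex (positive toward the apex); `septal_lateral` lies in the plane
#' spanned by the long axis and the aortic-annulus centroid (the LVOT plane),
#' orthogonalized against `basal_apical` and signed away from the aortic
#' centroid, i.e. toward the lateral wall; `inferior_anterior` completes the
#' right-handed triad (`basal_apical x septal_lateral`).
#'
#' @param landmarks a [landmark_set()].
#' @return list with unit vectors `basal_apical`, `septal_lateral`,
#'   `inferior_anterior` and `origin` (mitral centroid, mm); class
#'   `anatomical_frame`.
#' @export
build_frame <- function(landmarks) {
  validate_landmarks(landmarks)
  mc <- colMeans(landmarks$mitral_points)
  ac <- colMeans(landmarks$aortic_points)
  ba <- landmarks$apex - mc
  nba <- sqrt(sum(ba^2))
  if (nba < 1e-9) stop("degenerate geometry: apex at mitral centroid")
  ba <- ba / nba
  d <- ac - mc
  sl <- d - sum(d * ba) * ba
  nsl <- sqrt(sum(sl^2))
  if (nsl < 1e-9 * max(1, sqrt(sum(d^2)))) {
    stop("degenerate geometry: aortic centroid collinear with the long axis")
  }
  # septal wall lies on the LVOT/aorta side; lateral is the opposite sign
  sl <- -sl / nsl
  ia <- c(ba[2] * sl[3] - ba[3] * sl[2],
          ba[3] * sl[1] - ba[1] * sl[3],
          ba[1] * sl[2] - ba[2] * sl[1])
  structure(list(basal_apical = ba, septal_lateral = sl,
                 inferior_anterior = ia, origin = mc),
            class = "anatomical_frame")
}

#' Regional subdivision of the LV into basal, mid and apical slabs
#'
#' Two cutting planes perpendicular to the basal-apical axis pass through the
#' mean papillary-muscle tip and mean papillary-muscle base positions:
#' basal spans the mitral plane to the PM tips, mid the PM tips to the PM
#' bases, apical everything beyond the PM bases. By default the planes follow
#' the landmarks frame by frame; `fixed_at_ed = TRUE` freezes the end-diastolic
#' planes for the whole cycle.
#'
#' @param ds a [flow_dataset()] with PM landmarks.
#' @param fixed_at_ed use the frame-1 planes for all frames.
#' @return list with `labels`, a 4D integer array (1 basal, 2 mid, 3 apical,
#'   0 outside the mask); class `region_labels`.
#' @export
subdivide_regions <- function(ds, fixed_at_ed = FALSE) {
  g <- as_grid_frame(ds)
  d <- dim(g$mask)
  nt <- d[4]
  co <- grid_coords(d[1:3], g$spacing)
  labels <- array(0L, d)
  for (k in seq_len(nt)) {
    lm <- g$landmarks[[if (fixed_at_ed) 1 else k]]
    if (is.null(lm$pm_tips) || is.null(lm$pm_bases)) stop("PM landmarks are required")
    fr <- build_frame(lm)
    ba <- fr$basal_apical
    ell_tip <- mean(lm$pm_tips %*% ba)
    ell_base <- mean(lm$pm_bases %*% ba)
    if (ell_base <= ell_tip + 1e-9) {
      stop("geometry error: PM tip plane is not basal to the PM base plane")
    }
    # long-axis coordinate of every voxel centre
    lx <- outer(co$x * ba[1], co$y * ba[2], `+`)
    ell <- outer(as.vector(lx), co$z * ba[3], `+`)
    dim(ell) <- d[1:3]
    lab <- 1L + (ell > ell_tip) + (ell > ell_base)
    lab[!g$mask[, , , k]] <- 0L
    labels[, , , k] <- lab
  }
  structure(list(labels = labels), class = "region_labels")
}

# Fit a valve disc (centre, unit normal, radius) to an annulus point ring.
fit_disc <- function(points) {
  points <- rbind(points)
  if (nrow(points) < 3) stop("need >= 3 annulus points to fit a disc")
  ctr <- colMeans(points)
  p0 <- sweep(points, 2, ctr)
  sv <- svd(p0)
  normal <- sv$v[, 3]
  if (sv$d[2] < 1e-9) stop("degenerate annulus: points are collinear")
  radius <- mean(sqrt(rowSums(p0^2)))
  list(center = ctr, normal = unitize(normal), radius = radius)
}

# Equal-area quadrature points on a disc (grid-frame mm), plus point weight.
disc_quadrature <- function(disc, n_target = 400) {
  r <- disc$radius
  h <- 2 * r / ceiling(2 * sqrt(n_target / pi))
  s <- seq(-r + h / 2, r - h / 2, by = h)
  gxy <- expand.grid(a = s, b = s)
  keep <- gxy$a^2 + gxy$b^2 <= r^2
  gxy <- gxy[keep, ]
  n <- disc$normal
  e1 <- if (abs(n[1]) < 0.9) unitize(c(0, -n[3], n[2])) else unitize(c(-n[2], n[1], 0))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3], n[1] * e1[2] - n[2] * e1[1])
  pts <- outer(gxy$a, e1) + outer(gxy$b, e2)
  pts <- sweep(pts, 2, disc$center, `+`)
  list(points = pts, weight_mm2 = h * h)
}

#' Transvalvular flow-rate curve
#'
#' Integrates the velocity component normal to the valve disc over the disc,
#' per frame. The disc is fitted to the annulus point ring (centroid,
#' best-fit normal, radius = mean point distance from the centroid), and
#' velocity is sampled at equal-area quadrature points with mask-aware
#' trilinear interpolation. The sign convention makes diastolic inflow
#' positive for the mitral curve and systolic outflow positive for the aortic
#' curve.
#'
#' @param ds a [flow_dataset()].
#' @param which `"mitral"` or `"aortic"`.
#' @return numeric vector, mL/s per frame.
#' @export
transvalvular_flow <- function(ds, which = c("mitral", "aortic")) {
  which <- match.arg(which)
  g <- as_grid_frame(ds)
  nt <- dim(g$mask)[4]
  out <- numeric(nt)
  for (k in seq_len(nt)) {
    lm <- g$landmarks[[k]]
    disc <- fit_disc(lm[[paste0(which, "_points")]])
    # orient the normal: mitral inflow moves toward the apex, aortic outflow
    # away from it
    to_apex <- unitize(lm$apex - disc$center)
    sgn <- sum(disc$normal * to_apex)
    disc$normal <- disc$normal * sign(if (which == "mitral") sgn else -sgn)
    q <- disc_quadrature(disc)
    u <- sweep(q$points, 2, g$spacing, `/`) + 1
    m3 <- g$mask[, , , k] * 1
    vn <- numeric(nrow(u))
    for (c3 in 1:3) {
      vn <- vn + disc$normal[c3] * trilinear(g$velocity[, , , c3, k], u, w3 = m3)
    }
    # m/s * mm^2 -> mm^3/s * 1e3; report mL/s
    out[k] <- sum(vn) * q$weight_mm2 * 1e3 / 1e3
  }
  out
}

#' Cardiac phase detection from flow curves
#'
#' Systole runs from cycle start (end-diastole) to aortic valve closure,
#' identified as the downward zero crossing of the aortic flow curve after its
#' peak (sub-frame, by linear interpolation); diastole is the remainder of the
#' cycle. The E-peak is the first local maximum of the mitral flow curve in
#' diastole and the A-peak the last one, provided the two are separated by a
#' local minimum below both; otherwise the inflow is flagged merged and no
#' A-peak is reported. When no aortic curve is available the systole/diastole
#' boundary falls back to the volume-curve minimum.
#'
#' @param aortic_flow,mitral_flow mL/s per frame (aortic may be `NULL`).
#' @param frame_times s per frame; `rr_interval` cycle length, s.
#' @param volume_ml optional volume curve for the fallback boundary.
#' @param closure_threshold noise floor for the closure crossing, as a
#'   fraction of the aortic flow peak.
#' @return object of class `phase_map`: `systole`, `diastole` (time intervals),
#'   `aortic_valve_closure`, `e_peak`, `a_peak` (NA when merged), `merged`,
#'   `e_wave_window`, `a_wave_window`.
#' @export
detect_phases <- function(aortic_flow, mitral_flow, frame_times, rr_interval,
                          volume_ml = NULL, closure_threshold = 0.02) {
  nt <- length(frame_times)
  if (!is.null(aortic_flow)) {
    pk <- which.max(aortic_flow)
    if (aortic_flow[pk] <= 0) stop("phase detection failed: no aortic flow peak")
    # closure is where the flow falls through a small fraction of its peak:
    # a noise floor, so that a fluctuating zero tail of the sampled curve
    # cannot drag the detected closure into diastole. The induced early bias
    # is threshold/slope ~ 1% of systole, well below a half frame.
    thr <- closure_threshold * aortic_flow[pk]
    avc <- first_down_crossing(frame_times, aortic_flow, after = pk, threshold = thr)
    if (is.na(avc)) stop("phase detection failed: aortic flow never returns to zero")
  } else {
    if (is.null(volume_ml)) stop("need an aortic flow or a volume curve")
    avc <- frame_times[which.min(volume_ml)]
  }

  dia <- which(frame_times > avc)
  mf <- mitral_flow[dia]
  tf <- frame_times[dia]
  locmax <- which(diff(sign(diff(c(-Inf, mf, -Inf)))) < 0)
  locmax <- locmax[mf[locmax] > 1e-9 * max(mf)]
  if (!length(locmax)) stop("phase detection failed: no diastolic inflow peak")
  e_i <- locmax[1]; a_i <- locmax[length(locmax)]
  merged <- TRUE
  e_peak <- tf[e_i]; a_peak <- NA_real_
  mid_t <- rr_interval
  if (a_i > e_i) {
    between <- seq(e_i, a_i)
    m_i <- between[which.min(mf[between])]
    if (mf[m_i] < mf[e_i] && mf[m_i] < mf[a_i]) {
      merged <- FALSE
      a_peak <- tf[a_i]
      mid_t <- tf[m_i]
    }
  }
  structure(list(
    systole = c(0, avc), diastole = c(avc, rr_interval),
    aortic_valve_closure = avc,
    e_peak = e_peak, a_peak = a_peak, merged = merged,
    e_wave_window = c(avc, mid_t),
    a_wave_window = if (merged) NULL else c(mid_t, rr_interval)
  ), class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> systole [0, %.3f] s, diastole [%.3f, %.3f] s\n",
              x$aortic_valve_closure, x$aortic_valve_closure, x$diastole[2]))
  cat(sprintf("  E-peak %.3f s; A-peak %s\n", x$e_peak,
              if (x$merged) "merged/absent" else sprintf("%.3f s", x$a_peak)))
  invisible(x)
}

#' Dice score coefficient between two binary masks
#'
#' @param maskA,maskB logical arrays on the same grid.
#' @return `2|A & B| / (|A| + |B|)` in `[0, 1]`.
#' @export
dice <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB))) stop("masks must share a grid")
  a <- sum(maskA); b <- sum(maskB)
  if (a + b == 0) stop("Dice undefined: both masks are empty")
  2 * sum(maskA & maskB) / (a + b)
}

#' Random one-voxel boundary perturbation of a mask
#'
#' Flips a random subset of the mask's boundary layer (in-mask voxels with an
#' out-of-mask 6-neighbour are removed, out-of-mask voxels with an in-mask
#' 6-neighbour are added), emulating interoperator contouring differences.
#'
#' @param mask logical 3D array.
#' @param flip_prob probability that each boundary voxel flips.
#' @return perturbed logical array.
#' @export
perturb_mask <- function(mask, flip_prob = 0.5) {
  d <- dim(mask)
  has_out_nb <- array(FALSE, d); has_in_nb <- array(FALSE, d)
  for (ax in 1:3) for (by in c(-1, 1)) {
    has_out_nb <- has_out_nb | !nb(mask, ax, by, fill = FALSE)
    has_in_nb <- has_in_nb | nb(mask, ax, by, fill = FALSE)
  }
  inner_b <- which(mask & has_out_nb)
  outer_b <- which(!mask & has_in_nb)
  out <- mask
  out[inner_b[stats::runif(length(inner_b)) < flip_prob]] <- FALSE
  out[outer_b[stats::runif(length(outer_b)) < flip_prob]] <- TRUE
  out
}
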