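#' 4D flow dataset
#'
#' The central container of the pipeline: a time-resolved three-component
#' velocity field on a regular voxel grid, a binary left-ventricle mask on the
#' same grid, physical spacing, frame times over one cardiac cycle, and
#' anatomical landmarks per frame.
#'
#' Grid convention: voxel-centre coordinates; the centre of voxel
#' `(i, j, k)` (1-based) lies at `origin + orientation %*% ((c(i,j,k) - 1) * spacing)`
#' in world coordinates (mm). Time is cyclic with period `rr_interval`; the
#' first frame is end-diastole (`frame_times[1] == 0`). Velocity components
#' are stored along the grid axes (as phase-contrast acquisitions encode
#' them along image axes), in m/s; the `orientation` matrix maps them to
#' world vectors. Landmarks are world coordinates.
#'
#' @param velocity numeric 5D array `[nx, ny, nz, 3, nt]`, m/s, grid-axis
#'   components.
#' @param mask logical (or 0/1) 4D array `[nx, ny, nz, nt]`.
#' @param spacing numeric length-3, voxel edge lengths in mm.
#' @param frame_times numeric length-`nt`, s from cycle start; strictly
#'   increasing, first element 0, all `< rr_interval`.
#' @param rr_interval cycle length in s.
#' @param hematocrit haematocrit fraction in `[0, 1]`.
#' @param landmarks list of `nt` [landmark_set()] objects (or a single set,
#'   recycled to every frame).
#' @param origin world position of the centre of voxel (1,1,1), mm.
#' @param orientation 3x3 rotation matrix mapping grid axes to world axes.
#' @return an object of class `flow_dataset`.
#' @export
flow_dataset <- function(velocity, mask, spacing, frame_times, rr_interval,
                         hematocrit = 0.45, landmarks = NULL,
                         origin = c(0, 0, 0), orientation = diag(3)) {
  storage.mode(velocity) <- "double"
  mask <- array(as.logical(mask), dim(mask))
  dv <- dim(velocity); dm <- dim(mask)
  if (length(dv) != 5 || dv[4] != 3) stop("velocity must be [nx, ny, nz, 3, nt]")
  if (length(dm) != 4) stop("mask must be [nx, ny, nz, nt]")
  if (!all(dv[c(1, 2, 3, 5)] == dm)) stop("velocity and mask grids disagree in shape")
  nt <- dv[5]
  if (length(spacing) != 3 || any(spacing <= 0)) stop("spacing must be 3 positive lengths (mm)")
  if (length(frame_times) != nt) stop("frame_times length must equal the frame count")
  if (frame_times[1] != 0) stop("frame_times must start at 0 (end-diastole)")
  if (any(diff(frame_times) <= 0)) stop("frame_times must be strictly increasing")
  if (any(frame_times >= rr_interval)) stop("frame_times must all be < rr_interval")
  if (hematocrit < 0 || hematocrit > 1) stop("hematocrit must be in [0, 1]")
  for (k in seq_len(nt)) {
    if (!any(mask[, , , k])) stop(sprintf("mask is empty at frame %d", k))
  }
  if (!is.null(landmarks)) {
    if (inherits(landmarks, "landmark_set")) landmarks <- rep(list(landmarks), nt)
    if (length(landmarks) != nt) stop("need one landmark set per frame")
    lapply(landmarks, validate_landmarks)
  }
  orientation <- as.matrix(orientation)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-8) stop("orientation must be a rotation matrix")
  structure(list(
    velocity = velocity, mask = mask, spacing = as.numeric(spacing),
    frame_times = as.numeric(frame_times), rr_interval = rr_interval,
    hematocrit = hematocrit, landmarks = landmarks,
    origin = as.numeric(origin), orientation = orientation
  ), class = "flow_dataset")
}

#' @export
print.flow_dataset <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<flow_dataset> %d x %d x %d voxels, %d frames\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %s mm, RR %.3f s, hct %.2f\n",
              paste(signif(x$spacing, 4), collapse = " x "), x$rr_interval, x$hematocrit))
  cat(sprintf("  in-mask voxels at frame 1: %d (%.1f mL)\n",
              sum(x$mask[, , , 1]), sum(x$mask[, , , 1]) * prod(x$spacing) / 1000))
  invisible(x)
}

#' Anatomical landmark set for one frame
#'
#' All points are world coordinates in mm. The mitral and aortic annuli are
#' given as point rings (at least 3 points each so a plane can be fitted);
#' papillary-muscle (PM) tips and bases are one point per muscle.
#'
#' @param apex LV apex.
#' @param mitral_points matrix (>= 3 rows) of mitral annulus points.
#' @param aortic_points matrix (>= 3 rows) of aortic annulus points.
#' @param pm_tips matrix (2 rows) papillary-muscle tips.
#' @param pm_bases matrix (2 rows) papillary-muscle bases.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(apex, mitral_points, aortic_points, pm_tips = NULL, pm_bases = NULL) {
  as_pts <- function(p) {
    if (is.null(p)) return(NULL)
    p <- rbind(p)
    if (ncol(p) != 3) stop("landmark points must have 3 columns")
    storage.mode(p) <- "double"
    dimnames(p) <- NULL
    p
  }
  x <- structure(list(
    apex = as.numeric(apex),
    mitral_points = as_pts(mitral_points),
    aortic_points = as_pts(aortic_points),
    pm_tips = as_pts(pm_tips),
    pm_bases = as_pts(pm_bases)
  ), class = "landmark_set")
  validate_landmarks(x)
  x
}

validate_landmarks <- function(lm) {
  stopifnot(inherits(lm, "landmark_set") || is.list(lm))
  pts <- c(list(lm$apex), lapply(lm[c("mitral_points", "aortic_points", "pm_tips", "pm_bases")], identity))
  for (p in pts) if (!is.null(p) && any(!is.finite(p))) stop("landmarks must be finite")
  if (length(lm$apex) != 3) stop("apex must be a 3-vector")
  if (is.null(lm$mitral_points) || nrow(lm$mitral_points) < 3) stop("need >= 3 mitral annulus points")
  if (is.null(lm$aortic_points) || nrow(lm$aortic_points) < 3) stop("need >= 3 aortic annulus points")
  mc <- colMeans(lm$mitral_points)
  if (sqrt(sum((lm$apex - mc)^2)) < 1e-6) stop("apex coincides with the mitral centroid")
  invisible(lm)
}

# World -> grid-frame coordinates of points (rows), in mm relative to the
# centre of voxel (1,1,1), aligned with the grid axes.
world_to_grid <- function(ds, pts) {
  pts <- rbind(pts)
  sweep(pts, 2, ds$origin) %*% ds$orientation
}

# 1-based continuous voxel coordinates of world points.
world_to_voxel <- function(ds, pts) {
  g <- world_to_grid(ds, pts)
  sweep(g, 2, ds$spacing, `/`) + 1
}

# Grid-frame -> world.
grid_to_world <- function(ds, pts) {
  pts <- rbind(pts)
  sweep(pts %*% t(ds$orientation), 2, ds$origin, `+`)
}

transform_landmarks <- function(lm, fun) {
  out <- lm
  out$apex <- as.numeric(fun(rbind(lm$apex)))
  for (f in c("mitral_points", "aortic_points", "pm_tips", "pm_bases")) {
    if (!is.null(lm[[f]])) out[[f]] <- fun(lm[[f]])
  }
  out
}

#' Rotate a dataset (grid, vectors and landmarks) by a rotation matrix
#'
#' The voxel data are untouched: the grid orientation is composed with `R`
#' (so stored grid-axis velocity components are unchanged but map to rotated
#' world vectors) and landmarks are rotated about the world origin. Every
#' scalar quantity computed by the pipeline is invariant under this
#' operation to floating-point roundoff.
#'
#' @param ds a [flow_dataset()].
#' @param R 3x3 rotation matrix.
#' @return the rotated `flow_dataset`.
#' @export
rotate_dataset <- function(ds, R) {
  R <- as.matrix(R)
  lms <- ds$landmarks
  if (!is.null(lms)) lms <- lapply(lms, transform_landmarks, fun = function(p) p %*% t(R))
  flow_dataset(ds$velocity, ds$mask, ds$spacing, ds$frame_times, ds$rr_interval,
               hematocrit = ds$hematocrit, landmarks = lms,
               origin = as.numeric(R %*% ds$origin),
               orientation = R %*% ds$orientation)
}

# Re-express a dataset in its own grid-aligned frame (orientation = I,
# origin = 0): velocity arrays are already grid-axis components, so only the
# landmarks are mapped with t(Q). All operators call this first so that
# finite differences run along array axes.
as_grid_frame <- function(ds) {
  if (max(abs(ds$orientation - diag(3))) < 1e-15 && all(ds$origin == 0)) return(ds)
  lms <- ds$landmarks
  if (!is.null(lms)) {
    lms <- lapply(lms, transform_landmarks,
                  fun = function(p) sweep(p, 2, ds$origin) %*% ds$orientation)
  }
  flow_dataset(ds$velocity, ds$mask, ds$spacing, ds$frame_times, ds$rr_interval,
               hematocrit = ds$hematocrit, landmarks = lms)
}

# Voxel-centre coordinate arrays (grid frame, mm).
grid_coords <- function(dim3, spacing) {
  list(
    x = (seq_len(dim3[1]) - 1) * spacing[1],
    y = (seq_len(dim3[2]) - 1) * spacing[2],
    z = (seq_len(dim3[3]) - 1) * spacing[3]
  )
}

# Voxel volume in m^3 / mL.
voxel_volume_m3 <- function(spacing) prod(spacing) * 1e-9
voxel_volume_ml <- function(spacing) prod(spacing) / 1000
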