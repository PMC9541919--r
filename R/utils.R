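# Low-level array and interpolation utilities shared by the whole pipeline.
# Geometry is in mm, time in s, velocity in m/s; derived quantities are SI.

# Neighbour lookup: nb(x, axis, by)[i] == x[i + by] along `axis`,
# padded with `fill` outside the array.
nb <- function(x, axis, by, fill = NA) {
  d <- dim(x)
  n <- d[axis]
  if (abs(by) >= n) return(array(fill, d))
  out <- array(fill, d)
  dst <- src <- lapply(d, seq_len)
  if (by > 0) {
    dst[[axis]] <- seq_len(n - by)
    src[[axis]] <- seq_len(n - by) + by
  } else {
    dst[[axis]] <- seq_len(n + by) - by
    src[[axis]] <- seq_len(n + by)
  }
  out <- do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(x), src, list(drop = FALSE))))))
  out
}

nb_num <- function(x, axis, by) nb(x, axis, by, fill = 0)
nb_log <- function(x, axis, by) nb(x, axis, by, fill = FALSE)

# Stencil plans for masked finite differences: for each axis, linear-index
# sets of in-mask voxels by available stencil (central; second- and
# first-order one-sided; none = low-confidence). Computed once per mask and
# reused across all tensor components and operators.
deriv_plans <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  coords <- arrayInd(idx, d)
  strides <- c(1L, d[1], d[1] * d[2])
  lapply(1:3, function(ax) {
    s <- strides[ax]
    na <- d[ax]
    pos <- coords[, ax]
    nb_in <- function(off) {
      ok <- pos + off >= 1L & pos + off <= na
      r <- logical(length(idx))
      r[ok] <- mask[idx[ok] + off * s]
      r
    }
    mp <- nb_in(1L); mm <- nb_in(-1L); mpp <- nb_in(2L); mmm <- nb_in(-2L)
    list(s = s,
         cen = idx[mp & mm],
         f2 = idx[mp & !mm & mpp], f1 = idx[mp & !mm & !mpp],
         b2 = idx[mm & !mp & mmm], b1 = idx[mm & !mp & !mmm],
         low = idx[!mp & !mm])
  })
}

# Derivative of a scalar field from a per-axis stencil plan; h in mm, result
# per metre. Central differences in the interior, one-sided (second order
# where two aligned neighbours exist) at mask boundaries, 0 where no in-mask
# neighbour exists.
apply_deriv <- function(f, p, h) {
  hm <- h * 1e-3
  d <- array(0, dim(f))
  d[p$cen] <- (f[p$cen + p$s] - f[p$cen - p$s]) / (2 * hm)
  d[p$f2] <- (-3 * f[p$f2] + 4 * f[p$f2 + p$s] - f[p$f2 + 2L * p$s]) / (2 * hm)
  d[p$f1] <- (f[p$f1 + p$s] - f[p$f1]) / hm
  d[p$b2] <- (3 * f[p$b2] - 4 * f[p$b2 - p$s] + f[p$b2 - 2L * p$s]) / (2 * hm)
  d[p$b1] <- (f[p$b1] - f[p$b1 - p$s]) / hm
  d
}

#' Masked first derivative of a scalar field
#'
#' Central differences where both axis neighbours are inside the mask,
#' second-order one-sided stencils at mask boundaries (first-order when only
#' one aligned neighbour exists). Voxels with no in-mask axis neighbour get
#' derivative 0 and are flagged low-confidence.
#'
#' @param f numeric 3D array.
#' @param mask logical 3D array, same shape.
#' @param axis 1, 2 or 3.
#' @param h voxel spacing along `axis` in mm.
#' @return numeric 3D array, derivative per m, with attribute `lowconf`
#'   (logical array).
#' @keywords internal
masked_deriv <- function(f, mask, axis, h) {
  p <- deriv_plans(mask)[[axis]]
  d <- apply_deriv(f, p, h)
  low <- array(FALSE, dim(f))
  low[p$low] <- TRUE
  attr(d, "lowconf") <- low
  d
}

# Trilinear interpolation of a 3D array at continuous grid coordinates.
# `u` is an N x 3 matrix of 1-based voxel-centre coordinates (voxel (1,1,1)
# centre is at u = c(1,1,1)). Points outside the grid are clamped to the
# border. If `w3` (weights array, e.g. the mask) is supplied, interpolation is
# weight-normalised: corners with zero weight do not contribute; where all 8
# corner weights vanish the result is 0.
trilinear <- function(a, u, w3 = NULL) {
  d <- dim(a)
  n <- nrow(u)
  ui <- pmin(pmax(u[, 1], 1), d[1]); uj <- pmin(pmax(u[, 2], 1), d[2]); uk <- pmin(pmax(u[, 3], 1), d[3])
  i0 <- pmin(floor(ui), d[1] - 1); j0 <- pmin(floor(uj), d[2] - 1); k0 <- pmin(floor(uk), d[3] - 1)
  if (d[1] == 1) i0 <- rep(1, n)
  if (d[2] == 1) j0 <- rep(1, n)
  if (d[3] == 1) k0 <- rep(1, n)
  fi <- ui - i0; fj <- uj - j0; fk <- uk - k0
  nx <- d[1]; nxy <- d[1] * d[2]
  base <- (i0) + (j0 - 1) * nx + (k0 - 1) * nxy  # linear index of corner (i0,j0,k0)
  acc <- numeric(n); wacc <- numeric(n)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di == 1) fi else 1 - fi) * (if (dj == 1) fj else 1 - fj) * (if (dk == 1) fk else 1 - fk)
    idx <- base + di + dj * nx + dk * nxy
    if (is.null(w3)) {
      acc <- acc + w * a[idx]
    } else {
      wm <- w * w3[idx]
      acc <- acc + wm * a[idx]
      wacc <- wacc + wm
    }
  }
  if (is.null(w3)) acc else ifelse(wacc > 1e-12, acc / wacc, 0)
}

# Piecewise-linear curve utilities over one cyclic period ----------------

# Value of the piecewise-linear cyclic curve (times, values, period rr) at t.
cyclic_interp <- function(times, values, rr, t) {
  tt <- c(times, times[1] + rr)
  vv <- c(values, values[1])
  tq <- ((t - times[1]) %% rr) + times[1]
  stats::approx(tt, vv, xout = tq, rule = 2)$y
}

# Integral of the piecewise-linear cyclic curve from t0 to t1 (t1 >= t0,
# t1 - t0 <= rr). Endpoints may fall between samples.
cyclic_integral <- function(times, values, rr, t0, t1) {
  if (t1 < t0) stop("cyclic_integral: t1 < t0")
  # unwrap one period of knots covering [t0, t1]
  knots <- sort(unique(c(outer(times, c(-rr, 0, rr, 2 * rr), `+`))))
  knots <- knots[knots > t0 & knots < t1]
  grid <- c(t0, knots, t1)
  vals <- cyclic_interp(times, values, rr, grid)
  sum(diff(grid) * (vals[-length(vals)] + vals[-1]) / 2)
}

# Time-weighted mean over a window of a cyclic sampled curve.
cyclic_mean <- function(times, values, rr, t0, t1) {
  if (t1 <= t0) stop("cyclic_mean: empty window")
  cyclic_integral(times, values, rr, t0, t1) / (t1 - t0)
}

# Time-weighted RMS over a window.
cyclic_rms <- function(times, values, rr, t0, t1) {
  sqrt(cyclic_mean(times, values^2, rr, t0, t1))
}

# First downward crossing of `threshold` by a sampled curve after index
# `after` (linear interpolation between samples); returns NA when there is
# none. A small positive threshold makes the detection robust to
# roundoff-scale oscillation of a zero tail.
first_down_crossing <- function(times, values, after = 1, threshold = 0) {
  n <- length(values)
  for (k in seq(after, n - 1)) {
    if (values[k] > threshold && values[k + 1] <= threshold) {
      return(times[k] + (values[k] - threshold) / (values[k] - values[k + 1]) *
               (times[k + 1] - times[k]))
    }
  }
  NA_real_
}

# Rotation helpers -------------------------------------------------------

unitize <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("cannot normalize a near-zero vector")
  v / nv
}

# Random rotation matrix (uniform over SO(3)) from a given RNG state.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
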