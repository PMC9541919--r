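# Shared fixtures, built in code and memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# study-conditions phantom (default generator settings)
phantom_default <- function() memo("default", make_ellipsoid_lv())

# smaller, faster phantom for unit tests
phantom_small <- function() {
  memo("small", make_ellipsoid_lv(dim = c(26, 26, 40), n_frames = 20, edv = 100))
}

phases_of <- function(ph) {
  key <- paste0("phases_", format(utils::object.size(ph$dataset$velocity)))
  af <- transvalvular_flow(ph$dataset, "aortic")
  mf <- transvalvular_flow(ph$dataset, "mitral")
  detect_phases(af, mf, ph$dataset$frame_times, ph$dataset$rr_interval)
}

# uniform-flow tube whose whole pool enters through the bottom (mitral) disc
# in diastole and leaves through the top (aortic) disc in systole
straight_tube <- function(speed = 0.15, dim = c(14, 14, 26), spacing = c(2, 2, 2),
                          n_frames = 10, rr = 1) {
  vel <- array(0, c(dim, 3, n_frames))
  vel[, , , 3, ] <- speed
  mask <- array(TRUE, c(dim, n_frames))
  ext <- (dim - 1) * spacing
  cx <- ext[1] / 2; cy <- ext[2] / 2
  ring <- function(z, r) {
    ang <- seq(0, 2 * pi, length.out = 9)[-9]
    cbind(cx + r * cos(ang), cy + r * sin(ang), z)
  }
  lm <- landmark_set(apex = c(cx, cy, ext[3] / 2),
                     mitral_points = ring(0, 30),
                     aortic_points = ring(ext[3], 30))
  flow_dataset(vel, mask, spacing, (seq_len(n_frames) - 1) * rr / n_frames, rr,
               landmarks = lm)
}

manual_phases <- function(avc, rr) {
  structure(list(systole = c(0, avc), diastole = c(avc, rr),
                 aortic_valve_closure = avc,
                 e_peak = avc + 0.1 * (rr - avc), a_peak = NA_real_, merged = TRUE,
                 e_wave_window = c(avc, rr), a_wave_window = NULL),
            class = "phase_map")
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * max(abs(expected), .Machine$double.eps))
}
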