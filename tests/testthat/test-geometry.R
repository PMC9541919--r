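test_that("volumes: single voxel, rasterized sphere with convergence, phantom curve", {
  m <- array(FALSE, c(3, 3, 3, 1)); m[2, 2, 2, 1] <- TRUE
  expect_equal(lv_volume_series(m, c(2, 2, 2))$volume_ml, 0.008)

  sphere_vol <- function(h) {
    n <- ceiling(2 * 22 / h)
    co <- (seq_len(n) - 1) * h
    ctr <- max(co) / 2
    X <- array(rep(co - ctr, times = n * n), c(n, n, n))
    Y <- array(rep(rep(co - ctr, each = n), times = n), c(n, n, n))
    Z <- array(rep(co - ctr, each = n * n), c(n, n, n))
    m <- X^2 + Y^2 + Z^2 <= 20^2
    lv_volume_series(array(m, c(n, n, n, 1)), rep(h, 3))$volume_ml
  }
  v_true <- 4 / 3 * pi * 20^3 / 1000
  v1 <- sphere_vol(1)
  expect_rel_equal(v1, v_true, 0.02)
  e1 <- abs(v1 - v_true); e2 <- abs(sphere_vol(0.5) - v_true)
  expect_lt(e2, 0.6 * e1 + 1e-3 * v_true)

  ph <- phantom_default()
  v <- lv_volume_series(ph$dataset)$volume_ml
  expect_true(all(abs(v - ph$truth$volume_curve) / ph$truth$volume_curve < 0.03))

  m0 <- array(FALSE, c(3, 3, 3, 1)); m0[2, 2, 2, 1] <- TRUE; m0[] <- FALSE
  expect_error(lv_volume_series(m0, c(2, 2, 2)), "empty")
})

test_that("anatomical frame: axis-aligned example, orthonormality, equivariance", {
  ring <- function(ctr, r, n = 6) {
    ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    cbind(ctr[1] + r * cos(ang), ctr[2] + r * sin(ang), ctr[3])
  }
  lm <- landmark_set(apex = c(0, 0, -80),
                     mitral_points = ring(c(0, 0, 0), 15),
                     aortic_points = ring(c(20, 0, 5), 10))
  fr <- build_frame(lm)
  expect_equal(fr$basal_apical, c(0, 0, -1), tolerance = 1e-12)
  expect_equal(abs(fr$septal_lateral), c(1, 0, 0), tolerance = 1e-12)
  # right-handed: ba x sl = ia
  cr <- c(fr$basal_apical[2] * fr$septal_lateral[3] - fr$basal_apical[3] * fr$septal_lateral[2],
          fr$basal_apical[3] * fr$septal_lateral[1] - fr$basal_apical[1] * fr$septal_lateral[3],
          fr$basal_apical[1] * fr$septal_lateral[2] - fr$basal_apical[2] * fr$septal_lateral[1])
  expect_equal(cr, fr$inferior_anterior, tolerance = 1e-12)

  set.seed(3)
  for (i in 1:5) {
    apex <- rnorm(3, sd = 30)
    mc <- rnorm(3, sd = 10)
    ac <- mc + rnorm(3, sd = 20)
    lm <- landmark_set(apex = apex, mitral_points = ring(mc, 12),
                       aortic_points = ring(ac, 8))
    fr <- build_frame(lm)
    Tm <- cbind(fr$basal_apical, fr$septal_lateral, fr$inferior_anterior)
    expect_lt(max(abs(crossprod(Tm) - diag(3))), 1e-9)
    R <- lvflow:::random_rotation()
    lm_r <- lvflow:::transform_landmarks(lm, function(p) p %*% t(R))
    fr_r <- build_frame(lm_r)
    expect_equal(fr_r$basal_apical, as.numeric(R %*% fr$basal_apical), tolerance = 1e-9)
    expect_equal(fr_r$septal_lateral, as.numeric(R %*% fr$septal_lateral), tolerance = 1e-9)
  }

  # collinear aortic centroid -> degenerate geometry
  lm_bad <- landmark_set(apex = c(0, 0, -80), mitral_points = ring(c(0, 0, 0), 15),
                         aortic_points = ring(c(0, 0, 10), 1e-10))
  expect_error(build_frame(lm_bad), "degenerate")
})

test_that("regional subdivision partitions the mask and matches ellipsoid slab volumes", {
  ph <- phantom_small()
  labels <- subdivide_regions(ph$dataset)
  v <- lv_volume_series(ph$dataset, labels = labels)
  expect_equal(v$basal_ml + v$mid_ml + v$apical_ml, v$volume_ml, tolerance = 1e-12)

  # closed-form slab fractions of a half ellipsoid between PM planes
  slab <- function(u1, u2) (u2 - u2^3 / 3) - (u1 - u1^3 / 3)
  tot <- slab(0, 1)
  fr_true <- c(slab(0, 0.40), slab(0.40, 0.65), slab(0.65, 1)) / tot
  fr_meas <- c(v$basal_ml[1], v$mid_ml[1], v$apical_ml[1]) / v$volume_ml[1]
  # cut planes are tilted slightly (mitral centroid is off-axis), hence 3% + tilt slack
  expect_true(all(abs(fr_meas - fr_true) / fr_true < 0.05))

  # PM planes out of order
  ds2 <- ph$dataset
  ds2$landmarks <- lapply(ds2$landmarks, function(lm) {
    lm$pm_bases[, 3] <- lm$pm_tips[, 3]
    lm
  })
  expect_error(subdivide_regions(ds2), "PM tip plane")
})

test_that("transvalvular flow: uniform field through a disc, tangent field, phantom truth", {
  dimv <- c(24, 24, 24)
  vel <- array(0, c(dimv, 3, 3))
  vel[, , , 3, ] <- 0.5
  mask <- array(TRUE, c(dimv, 3))
  ctr <- (dimv - 1) * 2 / 2
  ring <- function(z, r) {
    ang <- seq(0, 2 * pi, length.out = 13)[-13]
    cbind(ctr[1] + r * cos(ang), ctr[2] + r * sin(ang), z)
  }
  lm <- landmark_set(apex = c(ctr[1], ctr[2], 0),
                     mitral_points = ring(30, 10), aortic_points = ring(40, 10))
  ds <- flow_dataset(vel, mask, c(2, 2, 2), c(0, 0.3, 0.6), 1, landmarks = lm)
  q_mi <- transvalvular_flow(ds, "mitral")   # inflow toward apex is negative here
  expect_rel_equal(abs(q_mi[1]), 0.5 * pi * 10^2, 0.02)
  # velocity tangent to the disc integrates to ~zero
  ds2 <- ds
  ds2$velocity[, , , 3, ] <- 0
  ds2$velocity[, , , 1, ] <- 0.5
  q_t <- transvalvular_flow(ds2, "mitral")
  expect_lt(abs(q_t[1]), 0.01 * 0.5 * pi * 10^2)

  ph <- phantom_small()
  af <- transvalvular_flow(ph$dataset, "aortic")
  pk <- which.max(ph$truth$aortic_flow)
  expect_rel_equal(af[pk], ph$truth$aortic_flow[pk], 0.05)
})

test_that("phase detection finds valve closure, E- and A-peaks, and flags merged inflow", {
  ph <- phantom_default()
  ds <- ph$dataset
  af <- transvalvular_flow(ds, "aortic")
  mf <- transvalvular_flow(ds, "mitral")
  p <- detect_phases(af, mf, ds$frame_times, ds$rr_interval)
  half_frame <- ds$rr_interval / length(ds$frame_times) / 2
  expect_lt(abs(p$aortic_valve_closure - ph$truth$avc_time), half_frame + 1e-9)
  expect_false(p$merged)
  expect_lt(p$e_peak, p$a_peak)

  phm <- make_ellipsoid_lv(e_to_a_ratio = Inf, dim = c(26, 26, 40), edv = 100,
                           n_frames = 20)
  afm <- transvalvular_flow(phm$dataset, "aortic")
  mfm <- transvalvular_flow(phm$dataset, "mitral")
  pm <- detect_phases(afm, mfm, phm$dataset$frame_times, phm$dataset$rr_interval)
  expect_true(pm$merged)
  expect_true(is.na(pm$a_peak))

  expect_error(detect_phases(rep(0, 20), mf[1:20], ds$frame_times[1:20],
                             ds$rr_interval), "no aortic flow peak")
})

test_that("Dice coefficient: identical, disjoint, shifted-cube and perturbation cases", {
  a <- array(FALSE, c(6, 6, 6))
  a[2:3, 2:3, 2:3] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, c(6, 6, 6))
  b[5, 5, 5] <- TRUE
  expect_equal(dice(a, b), 0)
  shifted <- array(FALSE, c(6, 6, 6))
  shifted[3:4, 2:3, 2:3] <- TRUE
  expect_equal(dice(a, shifted), 0.5)
  expect_error(dice(b & FALSE, b & FALSE), "empty")
  expect_error(dice(a, array(FALSE, c(5, 6, 6))), "share a grid")

  ph <- phantom_small()
  m <- ph$dataset$mask[, , , 1]
  set.seed(5)
  mp <- perturb_mask(m, 0.5)
  d <- dice(m, mp)
  expect_gt(d, 0.8)
  expect_lt(d, 1)
})
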