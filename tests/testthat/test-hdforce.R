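newt <- function(mu = 0.0035) rheology_params(model = "newtonian", newtonian_mu = mu)

test_that("pressure gradient: steady uniform flow, uniform ramp, Poiseuille", {
  un <- make_analytic_field("uniform", speed = 0.5, n_frames = 4)
  b <- pressure_gradient_field(un$dataset, 2, newt())
  expect_lt(max(abs(b$b)), 1e-9)
  fr <- build_frame(un$dataset$landmarks[[2]])
  h <- hemodynamic_force(b, un$dataset$spacing, fr, 100)
  expect_equal(unname(h$vector), c(0, 0, 0))

  ua <- make_analytic_field("uniform_acceleration", dim = c(25, 25, 20),
                            spacing = c(2, 2, 2), n_frames = 6, rr_interval = 1,
                            acceleration = 1)
  b2 <- pressure_gradient_field(ua$dataset, 3, newt())
  bx <- b2$b[, , , 1][b2$mask]
  expect_true(all(abs(bx - (-1025)) < 0.01 * 1025))
  expect_lt(max(abs(b2$b[, , , 2:3])), 1e-6)

  po <- make_analytic_field("poiseuille", dim = c(26, 26, 40), spacing = c(1, 1, 2),
                            v_max = 1, radius = 10, mu = 0.0035, n_frames = 3)
  b3 <- pressure_gradient_field(po$dataset, 2, newt())
  g <- velocity_gradient(po$dataset, 2)
  core <- b3$mask & !g$lowconf
  bz <- b3$b[, , , 3]
  expect_rel_equal(mean(bz[core]), -140, 0.05)
})

test_that("hemodynamic force integrates b over the chamber with unit bookkeeping", {
  ua <- make_analytic_field("uniform_acceleration", dim = c(25, 25, 20),
                            spacing = c(2, 2, 2), n_frames = 6, rr_interval = 1,
                            acceleration = 1)
  vol <- sum(ua$dataset$mask[, , , 1]) * prod(ua$dataset$spacing) / 1000
  expect_equal(vol, 100)
  b <- pressure_gradient_field(ua$dataset, 3, newt())
  fr <- build_frame(ua$dataset$landmarks[[3]])
  h <- hemodynamic_force(b, ua$dataset$spacing, fr, vol)
  expect_rel_equal(sqrt(sum(h$vector^2)), 0.1025, 0.01)
  expect_rel_equal(sqrt(sum(h$components_v^2)), 1.025, 0.01)
  # Pythagorean consistency of the triad decomposition
  expect_rel_equal(sum(h$components^2), sum(h$vector^2), 1e-9)
  # action-reaction convention flips the sign globally
  h2 <- hemodynamic_force(b, ua$dataset$spacing, fr, vol, convention = "wall_on_blood")
  expect_equal(h2$vector, -h$vector)
})

test_that("variable-viscosity path equals the Newtonian path when mu is constant", {
  ph <- phantom_small()
  const_cy <- rheology_params(mu_zero = 0.0035, mu_inf = 0.0035,
                              hct_reference = ph$dataset$hematocrit)
  b1 <- pressure_gradient_field(ph$dataset, 4, newt(0.0035))
  b2 <- pressure_gradient_field(ph$dataset, 4, const_cy)
  expect_equal(b1$b, b2$b, tolerance = 1e-12)
})

test_that("RMS summaries and R_RMS follow the transversal/longitudinal definition", {
  nt <- 20
  tt <- (0:(nt - 1)) * 0.05
  mk_series <- function(ba, sl, ia) {
    structure(list(samples = data.frame(
      frame = 1:nt, time = tt, fx = 0, fy = 0, fz = 0,
      basal_apical = ba, septal_lateral = sl, inferior_anterior = ia,
      basal_apical_v = ba, septal_lateral_v = sl, inferior_anterior_v = ia,
      volume_ml = 100), frame_times = tt, rr_interval = 1),
      class = "hdf_series")
  }
  phs <- manual_phases(0.4, 1)
  s1 <- summarize_hdf(mk_series(sin(2 * pi * tt), 0, 0), phs)
  expect_equal(unname(s1$r_rms), c(0, 0))
  x <- cos(2 * pi * tt) + 0.2
  s2 <- summarize_hdf(mk_series(x, x, x), phs)
  expect_equal(unname(s2$r_rms), c(sqrt(2), sqrt(2)), tolerance = 1e-9)
  expect_error(summarize_hdf(mk_series(rep(0, nt), x, x), phs), "undefined")

  # long-axis-aligned axisymmetric phantom: force stays near the long axis
  ph <- phantom_small()
  hdf <- compute_hdf_series(ph$dataset)
  hs <- summarize_hdf(hdf, phases_of(ph))
  expect_lt(hs$r_rms["systole"], 0.2)
  expect_lt(hs$r_rms["diastole"], 0.2)
})

test_that("filling impulse: hand-computed trapezoid, undefined case, sub-frame endpoints", {
  tt <- seq(0, 0.95, by = 0.05)
  nt <- length(tt)
  ba <- numeric(nt)
  ba[tt >= 0.4 & tt <= 0.5] <- -0.5
  ba[tt > 0.5] <- 0.5
  # linear crossing between 0.5 (-0.5) and 0.55 (+0.5) -> zero at 0.525
  ser <- structure(list(samples = data.frame(
    frame = 1:nt, time = tt, fx = 0, fy = 0, fz = 0,
    basal_apical = ba, septal_lateral = 0, inferior_anterior = 0,
    basal_apical_v = ba, septal_lateral_v = 0, inferior_anterior_v = 0,
    volume_ml = 100), frame_times = tt, rr_interval = 1),
    class = "hdf_series")
  phs <- manual_phases(0.4, 1)
  imp <- filling_impulse(ser, phs)
  expect_true(imp$defined)
  expect_equal(imp$t_end, 0.525, tolerance = 1e-9)
  # integral: -0.5 over [0.4, 0.5] plus the triangle to the crossing
  expect_equal(imp$impulse, -0.5 * 0.1 - 0.5 * 0.025 / 2, tolerance = 1e-9)
  expect_equal(imp$magnitude, abs(imp$impulse))

  ser0 <- ser
  ser0$samples$basal_apical_v <- 0
  imp0 <- filling_impulse(ser0, phs)
  expect_false(imp0$defined)
})

test_that("rotating the dataset leaves projected components, R_RMS and impulse unchanged", {
  ph <- phantom_small()
  set.seed(21)
  R <- lvflow:::random_rotation()
  dsr <- rotate_dataset(ph$dataset, R)
  phs <- phases_of(ph)
  h1 <- compute_hdf_series(ph$dataset)
  h2 <- compute_hdf_series(dsr)
  for (cn in c("basal_apical_v", "septal_lateral_v", "inferior_anterior_v")) {
    expect_lt(max(abs(h1$samples[[cn]] - h2$samples[[cn]])),
              1e-6 * max(abs(h1$samples$basal_apical_v)))
  }
  s1 <- summarize_hdf(h1, phs); s2 <- summarize_hdf(h2, phs)
  expect_equal(s1$r_rms, s2$r_rms, tolerance = 1e-6)
  i1 <- filling_impulse(h1, phs); i2 <- filling_impulse(h2, phs)
  expect_equal(i1$impulse, i2$impulse, tolerance = 1e-6 * abs(i1$impulse))
  # the world vector itself rotates with R
  v1 <- as.matrix(h1$samples[, c("fx", "fy", "fz")])
  v2 <- as.matrix(h2$samples[, c("fx", "fy", "fz")])
  expect_lt(max(abs(v2 - v1 %*% t(R))), 1e-9 * max(abs(v1)))
})
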