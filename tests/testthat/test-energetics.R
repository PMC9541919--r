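test_that("kinetic energy: single voxel, zero field, rotating cylinder closed form", {
  dimv <- c(3, 3, 3)
  vel <- array(0, c(dimv, 3, 3))
  vel[2, 2, 2, 1, 1] <- 1
  m <- array(FALSE, c(dimv, 3)); m[2, 2, 2, ] <- TRUE
  ds <- flow_dataset(vel, m, c(2, 2, 2), c(0, 0.3, 0.6), 1)
  expect_equal(unname(kinetic_energy(ds, 1, density = 1025)["global"]),
               0.5 * 1025 * 8e-9, tolerance = 1e-12)
  expect_equal(unname(kinetic_energy(ds, 2)["global"]), 0)

  rr <- make_analytic_field("rigid_rotation", omega = 10, radius = 18,
                            dim = c(24, 24, 24), spacing = c(2, 2, 2))
  ke <- kinetic_energy(rr$dataset, 1)
  expect_rel_equal(unname(ke["global"]), rr$truth$ke_j, 0.02)
})

test_that("viscous loss: rigid rotation and uniform flow dissipate nothing", {
  rr <- make_analytic_field("rigid_rotation", omega = 10, radius = 18)
  ke_rate_scale <- unname(kinetic_energy(rr$dataset, 1)["global"]) / rr$dataset$rr_interval
  el <- unname(viscous_loss_rate(rr$dataset, 1, rheology_params(model = "newtonian"))["global"])
  expect_lt(abs(el), 1e-10 * ke_rate_scale)
  un <- make_analytic_field("uniform", speed = 0.5)
  expect_equal(unname(viscous_loss_rate(un$dataset, 1)["global"]), 0)
})

test_that("Poiseuille dissipation matches the closed form, halving under refinement", {
  newt <- rheology_params(model = "newtonian", newtonian_mu = 0.0035)
  err_at <- function(h, off) {
    n_xy <- ceiling(26 / h)
    n_z <- ceiling(80 / (2 * h))
    fld <- make_analytic_field("poiseuille", dim = c(n_xy, n_xy, n_z),
                               spacing = c(h, h, 2 * h), v_max = 1, radius = 10,
                               mu = 0.0035, center_offset = off * h)
    el <- unname(viscous_loss_rate(fld$dataset, 1, newt)["global"])
    truth <- 2 * pi * 0.0035 * 1^2 * (n_z * 2 * h * 1e-3)
    abs(el - truth) / truth
  }
  # rasterized-boundary quadrature error oscillates with grid alignment, so
  # convergence is measured in expectation over sub-voxel tube placements
  set.seed(31)
  offs <- matrix(stats::runif(8) - 0.5, 4, 2)
  e1 <- vapply(seq_len(4), function(i) err_at(1, offs[i, ]), numeric(1))
  expect_lt(max(e1), 0.05)
  e2 <- vapply(seq_len(4), function(i) err_at(0.5, offs[i, ]), numeric(1))
  expect_lt(mean(e2), 0.6 * mean(e1) + 0.002)
})

test_that("quadratic scaling and regional additivity are exact", {
  ph <- phantom_small()
  ds <- ph$dataset
  labels <- subdivide_regions(ds)
  k <- 6
  ke <- kinetic_energy(ds, k, labels = labels)
  el <- viscous_loss_rate(ds, k, rheology_params(model = "newtonian"), labels = labels)
  expect_equal(unname(ke["global"]), unname(sum(ke[c("basal", "mid", "apical")])),
               tolerance = 1e-12)
  expect_equal(unname(el["global"]), unname(sum(el[c("basal", "mid", "apical")])),
               tolerance = 1e-12)
  ds2 <- ds
  ds2$velocity <- ds$velocity * 2
  expect_equal(unname(kinetic_energy(ds2, k)["global"]), 4 * unname(ke["global"]),
               tolerance = 1e-12)
  expect_equal(unname(viscous_loss_rate(ds2, k, rheology_params(model = "newtonian"))["global"]),
               4 * unname(el["global"]), tolerance = 1e-12)
  expect_true(all(ke >= 0))
})

test_that("volume normalization and peak extraction behave as specified", {
  # constant 5 mJ at constant 100 mL -> 0.05 J/L at all frames
  nt <- 10
  tt <- (0:(nt - 1)) * 0.1
  phases <- manual_phases(0.35, 1)
  en <- normalize_and_summarize(rep(0.005, nt), rep(1e-4, nt), rep(100, nt),
                                phases, tt, 1)
  expect_true(all(abs(en$ke_v[, "global"] - 0.05) < 1e-12))

  # E-wave KE_V peak time agrees with a finely time-sampled oracle phantom
  # (the phantom's KE_V peak leads the flow E-peak because the normalized
  # inflow rate dV/dt / V peaks earlier than dV/dt)
  ph <- phantom_default()
  ds <- ph$dataset
  af <- transvalvular_flow(ds, "aortic")
  mf <- transvalvular_flow(ds, "mitral")
  phs <- detect_phases(af, mf, ds$frame_times, ds$rr_interval)
  ntf <- length(ds$frame_times)
  ke <- vapply(seq_len(ntf), function(k) unname(kinetic_energy(ds, k)["global"]), numeric(1))
  el <- rep(0, ntf)
  vol <- lv_volume_series(ds)$volume_ml
  en <- normalize_and_summarize(ke, el, vol, phs, ds$frame_times, ds$rr_interval)
  pk_t <- en$peaks$time[en$peaks$peak == "e_wave" & en$peaks$region == "global"]

  fine <- make_ellipsoid_lv(n_frames = 120)
  dsf <- fine$dataset
  kef <- vapply(1:120, function(k) unname(kinetic_energy(dsf, k)["global"]), numeric(1))
  volf <- lv_volume_series(dsf)$volume_ml
  w <- dsf$frame_times > fine$truth$avc_time &
    dsf$frame_times < (fine$truth$e_peak_time + fine$truth$a_peak_time) / 2
  t_oracle <- dsf$frame_times[w][which.max((kef / volf)[w])]
  half_frame <- ds$rr_interval / ntf / 2
  expect_lt(abs(pk_t - t_oracle), half_frame + ds$rr_interval / 120 / 2 + 1e-9)
  expect_error(normalize_and_summarize(ke, el, vol * 0, phs, ds$frame_times,
                                       ds$rr_interval), "volume")
})

test_that("a reduced-ejection-fraction phantom has a lower systolic KE_V peak", {
  base <- make_ellipsoid_lv(edv = 100, ef = 0.65, dim = c(26, 26, 40), n_frames = 20)
  low <- make_ellipsoid_lv(edv = 100, ef = 0.30, dim = c(26, 26, 40), n_frames = 20)
  pk <- function(ph) {
    ds <- ph$dataset
    ntf <- length(ds$frame_times)
    ke <- vapply(seq_len(ntf), function(k) unname(kinetic_energy(ds, k)["global"]), numeric(1))
    vol <- lv_volume_series(ds)$volume_ml
    sys <- ds$frame_times <= ph$truth$avc_time
    max(ke[sys] / (vol[sys] / 1000))
  }
  expect_lt(pk(low), pk(base))
})
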