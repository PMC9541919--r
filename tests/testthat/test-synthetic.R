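test_that("analytic truths match brute-force finite differences before use as oracles", {
  # Poiseuille: differentiate the analytic profile numerically on a fine grid
  v_max <- 1; R <- 10; mu <- 0.0035
  vz <- function(x, y) v_max * (1 - (x^2 + y^2) / R^2)
  h <- 1e-4
  x0 <- 3; y0 <- -4
  lap <- (vz(x0 + h, y0) + vz(x0 - h, y0) + vz(x0, y0 + h) + vz(x0, y0 - h) -
            4 * vz(x0, y0)) / h^2          # per mm^2
  b_axial_fd <- mu * lap * 1e6             # Pa/m
  fld <- make_analytic_field("poiseuille", v_max = v_max, radius = R, mu = mu)
  expect_rel_equal(fld$truth$pressure_gradient[3], b_axial_fd, 1e-6)
  expect_equal(fld$truth$pressure_gradient[3], -140)

  # dissipation: dense numerical quadrature of mu * gamma_dot^2 over the tube
  rs <- seq(0.0005, R - 0.0005, by = 0.001)
  gd <- 2 * v_max * rs / R^2 * 1e3         # 1/s (rs in mm)
  L <- prod(c(40) * 2) * 1e-3              # 40 slices at 2 mm, in m
  diss_quad <- sum(mu * gd^2 * 2 * pi * rs * 0.001) * 1e-6 * L
  fld2 <- make_analytic_field("poiseuille", dim = c(24, 24, 40), spacing = c(2, 2, 2),
                              v_max = v_max, radius = R, mu = mu)
  expect_rel_equal(fld2$truth$dissipation_w[1], diss_quad, 1e-4)
})

test_that("rigid rotation and uniform flow carry zero-truth values", {
  rr <- make_analytic_field("rigid_rotation", omega = 10)
  expect_true(all(rr$truth$dissipation_w == 0))
  un <- make_analytic_field("uniform", speed = 0.5)
  expect_true(all(un$truth$hdf_n == 0))
  ua <- make_analytic_field("uniform_acceleration", acceleration = 2)
  expect_equal(ua$truth$pressure_gradient, c(-2050, 0, 0))
})

test_that("phantom volumetrics are definitional", {
  ph <- make_ellipsoid_lv(edv = 150, ef = 0.6, dim = c(30, 30, 44), n_frames = 16)
  expect_equal(ph$truth$sv, 90)
  expect_equal(ph$truth$esv, 60)
  expect_equal(max(ph$truth$volume_curve), 150)
  expect_equal(ph$truth$ef, ph$truth$sv / max(ph$truth$volume_curve))
  expect_error(make_ellipsoid_lv(ef = 1.2), "ef must be")
  expect_error(make_ellipsoid_lv(systole_fraction = 1.4), "systole_fraction")
  expect_error(make_ellipsoid_lv(e_to_a_ratio = -1), "e_to_a_ratio")
})

test_that("prescribed E/A peak-flow ratio is recovered from the generated inflow model", {
  ph <- make_ellipsoid_lv(e_to_a_ratio = 2, dim = c(26, 26, 40), edv = 100, n_frames = 20)
  tt <- seq(ph$truth$avc_time, ph$truth$rr_interval, by = 1e-4)
  inflow <- ph$truth$dvdt_fun(tt)
  # two separated humps: E first, A last
  e_pk <- max(inflow[tt < ph$truth$avc_time + 0.5 * (ph$truth$rr_interval - ph$truth$avc_time)])
  a_pk <- max(inflow[tt > ph$truth$rr_interval - 0.3 * (ph$truth$rr_interval - ph$truth$avc_time)])
  expect_rel_equal(e_pk / a_pk, 2, 0.01)
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- make_ellipsoid_lv(dim = c(24, 24, 32), edv = 60, n_frames = 8,
                         noise_sd = 0.02, seed = 42)
  b <- make_ellipsoid_lv(dim = c(24, 24, 32), edv = 60, n_frames = 8,
                         noise_sd = 0.02, seed = 42)
  expect_identical(a$dataset$velocity, b$dataset$velocity)
  c <- make_ellipsoid_lv(dim = c(24, 24, 32), edv = 60, n_frames = 8,
                         noise_sd = 0.02, seed = 43)
  expect_false(identical(a$dataset$velocity, c$dataset$velocity))
})

test_that("orifice flux matches dV/dt within the discretization bound, halving on refinement", {
  flux_err <- function(dim, spacing) {
    ph <- make_ellipsoid_lv(edv = 150, dim = dim, spacing = spacing, n_frames = 20)
    af <- transvalvular_flow(ph$dataset, "aortic")
    mf <- transvalvular_flow(ph$dataset, "mitral")
    truth_a <- ph$truth$aortic_flow
    truth_m <- ph$truth$mitral_flow
    ks <- which(truth_a > 0.5 * max(truth_a))
    km <- which(truth_m > 0.5 * max(truth_m))
    max(abs(af[ks] - truth_a[ks]) / truth_a[ks],
        abs(mf[km] - truth_m[km]) / truth_m[km])
  }
  e1 <- flux_err(c(32, 32, 48), c(2.5, 2.5, 2.5))
  expect_lt(e1, 0.03)
  e2 <- flux_err(c(64, 64, 96), c(1.25, 1.25, 1.25))
  expect_lt(e2, 0.6 * e1 + 0.005)
})

test_that("merged-inflow phantom produces a single diastolic hump", {
  ph <- make_ellipsoid_lv(e_to_a_ratio = Inf, dim = c(26, 26, 40), edv = 100,
                          n_frames = 20)
  expect_true(ph$truth$merged_inflow)
  tt <- seq(ph$truth$avc_time + 1e-6, ph$truth$rr_interval - 1e-6, by = 1e-3)
  inflow <- ph$truth$dvdt_fun(tt)
  sgn <- diff(sign(diff(inflow)))
  expect_equal(sum(sgn < 0), 1)  # exactly one local maximum
})
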