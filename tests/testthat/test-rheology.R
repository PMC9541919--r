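linear_field_ds <- function(fill) {
  dimv <- c(12, 12, 12)
  co <- grid <- (seq_len(12) - 1) * 2
  vel <- array(0, c(dimv, 3, 3))
  X <- array(rep(co, times = 144), dimv)
  Y <- array(rep(rep(co, each = 12), times = 12), dimv)
  Z <- array(rep(co, each = 144), dimv)
  fill(vel, X, Y, Z)
}

test_that("gradient and shear rate on linear fields are exact", {
  dimv <- c(12, 12, 12)
  co <- (seq_len(12) - 1) * 2
  Y <- array(rep(rep(co, each = 12), times = 12), dimv)
  vel <- array(0, c(dimv, 3, 3))
  for (k in 1:3) vel[, , , 1, k] <- 10 * Y * 1e-3  # v_x = k y, k = 10 /s
  ds <- flow_dataset(vel, array(TRUE, c(dimv, 3)), c(2, 2, 2), c(0, 0.3, 0.6), 1)
  g <- velocity_gradient(ds, 1)
  expect_lt(max(abs(g$g[, , , 1, 2] - 10)), 1e-9)
  other <- g$g; other[, , , 1, 2] <- 0
  expect_lt(max(abs(other)), 1e-9)
  gd <- shear_rate(g)
  expect_lt(max(abs(gd - 10)), 1e-9)

  # uniform field: zero tensor
  vel[] <- 0.4
  ds0 <- flow_dataset(vel, array(TRUE, c(dimv, 3)), c(2, 2, 2), c(0, 0.3, 0.6), 1)
  expect_lt(max(abs(velocity_gradient(ds0, 1)$g)), 1e-12)

  # rigid rotation: antisymmetric tensor, zero strain rate in the interior
  rr <- make_analytic_field("rigid_rotation", omega = 10, radius = 16)
  gr <- velocity_gradient(rr$dataset, 1)
  S12 <- (gr$g[, , , 1, 2] + gr$g[, , , 2, 1]) / 2
  core <- gr$mask & !gr$lowconf
  expect_lt(max(abs(S12[core])), 1e-9)
  gd_r <- shear_rate(gr)
  expect_lt(max(gd_r[core]), 1e-9)
})

test_that("Poiseuille shear rate peaks at the wall with value 2 v_max / R", {
  fld <- make_analytic_field("poiseuille", dim = c(26, 26, 20), spacing = c(1, 1, 2),
                             v_max = 1, radius = 10)
  g <- velocity_gradient(fld$dataset, 1)
  gd <- shear_rate(g)
  expect_rel_equal(max(gd), 2 * 1 / 0.01, 0.08)
  # linear in r: at half radius, half the wall value
  co <- (seq_len(26) - 1) * 1
  ctr <- max(co) / 2
  X <- array(rep(co - ctr, times = 26 * 20), c(26, 26, 20))
  Y <- array(rep(rep(co - ctr, each = 26), times = 20), c(26, 26, 20))
  mid <- abs(sqrt(X^2 + Y^2) - 5) < 0.3 & g$mask
  expect_rel_equal(mean(gd[mid]), 100, 0.05)
})

test_that("viscosity model: Newtonian constant, Carreau-Yasuda limits, bounds, hct monotonicity", {
  gd <- 10^seq(-3, 5, length.out = 200)
  p <- rheology_params()
  expect_equal(unique(as.numeric(viscosity(gd, 0.45, rheology_params(model = "newtonian")))),
               0.0035)
  mu <- viscosity(gd, p$hct_reference, p)
  expect_true(all(mu <= p$mu_zero + 1e-15 & mu >= p$mu_inf - 1e-15))
  expect_true(all(diff(mu) < 0))  # shear thinning: monotone decay to mu_inf
  expect_rel_equal(viscosity(1e6 / p$relaxation_time, p$hct_reference, p), p$mu_inf, 0.01)
  expect_rel_equal(viscosity(0, p$hct_reference, p), p$mu_zero, 1e-12)
  mu35 <- viscosity(gd, 0.35, p)
  mu45 <- viscosity(gd, 0.45, p)
  expect_true(all(mu35 < mu45))
  expect_error(rheology_params(mu_zero = 0.001, mu_inf = 0.003), "non-physical")
  expect_error(viscosity(gd, 1.2, p), "hematocrit")
})

test_that("shear rate is frame-indifferent and the gradient converges at second order", {
  ph <- phantom_small()
  set.seed(9)
  R <- lvflow:::random_rotation()
  dsr <- rotate_dataset(ph$dataset, R)
  g1 <- shear_rate(velocity_gradient(ph$dataset, 5))
  g2 <- shear_rate(velocity_gradient(dsr, 5))
  expect_lt(max(abs(g1 - g2)), 1e-6 * max(g1))

  # smooth trigonometric field: interior error ~ h^2
  gerr <- function(h) {
    n <- round(24 / h)
    co <- (seq_len(n) - 1) * h
    X <- array(rep(co, times = n * n), c(n, n, n))
    vel <- array(0, c(n, n, n, 3, 3))
    for (k in 1:3) vel[, , , 2, k] <- sin(X / 8)
    ds <- flow_dataset(vel, array(TRUE, c(n, n, n, 3)), rep(h, 3), c(0, 0.3, 0.6), 1)
    g <- velocity_gradient(ds, 1)
    truth <- cos(X / 8) / 8 * 1e3
    core <- !g$lowconf
    max(abs(g$g[, , , 2, 1] - truth)[core])
  }
  e1 <- gerr(2); e2 <- gerr(1)
  expect_lt(e2, 0.35 * e1)
})
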