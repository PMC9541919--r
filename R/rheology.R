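#' Blood rheology parameters
#'
#' Blood is modelled as an incompressible fluid of density 1025 kg/m3 whose
#' viscosity depends on shear rate and haematocrit. The default constitutive
#' law is a Carreau-Yasuda model,
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)\,[1+(\lambda\dot\gamma)^a]^{(n-1)/a},}
#' with the asymptotic viscosities scaled by haematocrit through a
#' Krieger-Dougherty-type factor `((1-hct)/(1-hct_ref))^-2.5`. The default
#' constants (`mu_zero` 0.056 Pa s, `mu_inf` 0.00345 Pa s, `relaxation_time`
#' 3.313 s, `power_index` 0.3568, `transition` 2) are standard whole-blood
#' values at the 0.45 reference haematocrit; all are overridable. A Newtonian
#' model (`newtonian_mu`, default 3.5 mPa s) is available for analytic
#' verification work.
#'
#' @param model `"carreau_yasuda_hct"` or `"newtonian"`.
#' @param density kg/m3.
#' @param mu_zero,mu_inf zero- and infinite-shear viscosities, Pa s.
#' @param relaxation_time s; `power_index`, `transition` dimensionless.
#' @param hct_reference haematocrit at which `mu_zero`/`mu_inf` apply.
#' @param newtonian_mu Pa s, used when `model = "newtonian"`.
#' @return list of class `rheology_params`.
#' @export
rheology_params <- function(model = c("carreau_yasuda_hct", "newtonian"),
                            density = 1025,
                            mu_zero = 0.056, mu_inf = 0.00345,
                            relaxation_time = 3.313, power_index = 0.3568,
                            transition = 2, hct_reference = 0.45,
                            newtonian_mu = 0.0035) {
  model <- match.arg(model)
  if (density <= 0) stop("density must be positive")
  if (mu_zero < mu_inf) stop("non-physical rheology: mu_zero < mu_inf")
  if (any(c(mu_inf, relaxation_time, power_index, transition, newtonian_mu) <= 0)) {
    stop("rheology constants must be positive")
  }
  if (hct_reference <= 0 || hct_reference >= 1) stop("hct_reference must be in (0, 1)")
  structure(list(model = model, density = density, mu_zero = mu_zero,
                 mu_inf = mu_inf, relaxation_time = relaxation_time,
                 power_index = power_index, transition = transition,
                 hct_reference = hct_reference, newtonian_mu = newtonian_mu),
            class = "rheology_params")
}

#' Velocity-gradient tensor field of one frame
#'
#' Component `(i, j)` is `dv_i/dx_j` in 1/s, from central differences in the
#' mask interior and one-sided differences (second order where possible) at
#' mask boundaries. Voxels with no in-mask neighbour along an axis get a zero
#' derivative along that axis and are flagged low-confidence.
#'
#' @param ds a [flow_dataset()] (internally mapped to its grid frame).
#' @param frame frame index.
#' @return list with `g`, a 5D array `[nx, ny, nz, 3, 3]` (1/s, grid-frame
#'   components), `mask` and `lowconf`.
#' @export
velocity_gradient <- function(ds, frame = 1) {
  g <- as_grid_frame(ds)
  m <- g$mask[, , , frame]
  d3 <- dim(m)
  plans <- deriv_plans(m)
  out <- array(0, c(d3, 3, 3))
  low <- array(FALSE, d3)
  for (j in 1:3) low[plans[[j]]$low] <- TRUE
  for (i in 1:3) {
    vi <- g$velocity[, , , i, frame]
    for (j in 1:3) {
      out[, , , i, j] <- apply_deriv(vi, plans[[j]], g$spacing[j])
    }
  }
  list(g = out, mask = m, lowconf = low, spacing = g$spacing, plans = plans)
}

# S:S, the double contraction of the strain-rate tensor, from a gradient
# tensor array [nx,ny,nz,3,3]; returns a 3D array (1/s^2).
strain_double_dot <- function(gt) {
  ss <- 0
  for (i in 1:3) for (j in 1:3) {
    s_ij <- (gt[, , , i, j] + gt[, , , j, i]) / 2
    ss <- ss + s_ij^2
  }
  ss
}

#' Scalar shear-rate field
#'
#' `gamma_dot = sqrt(2 S:S)` with `S` the symmetric part of the velocity
#' gradient; this normalization recovers `|k|` for the simple shear
#' `v_x = k y`.
#'
#' @param grad result of [velocity_gradient()].
#' @return 3D array, 1/s (zero outside the mask).
#' @export
shear_rate <- function(grad) {
  g <- sqrt(2 * strain_double_dot(grad$g))
  g[!grad$mask] <- 0
  g
}

#' Dynamic viscosity field
#'
#' @param gamma_dot shear-rate field (1/s), e.g. from [shear_rate()].
#' @param hematocrit fraction in `[0, 1]`.
#' @param params a [rheology_params()].
#' @return array of viscosities, Pa s (same shape as `gamma_dot`).
#' @export
viscosity <- function(gamma_dot, hematocrit, params = rheology_params()) {
  if (hematocrit < 0 || hematocrit > 1) stop("hematocrit must be in [0, 1]")
  if (params$model == "newtonian") {
    return(array(params$newtonian_mu, dim(gamma_dot) %||% length(gamma_dot)))
  }
  scale <- ((1 - hematocrit) / (1 - params$hct_reference))^(-2.5)
  mu0 <- params$mu_zero * scale
  muI <- params$mu_inf * scale
  a <- params$transition
  n <- params$power_index
  lam <- params$relaxation_time
  muI + (mu0 - muI) * (1 + (lam * gamma_dot)^a)^((n - 1) / a)
}
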