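#!/usr/bin/env Rscript
# Verify the energy and force operators against analytic fields with
# closed-form answers: rigid rotation (zero dissipation), uniform flow (zero
# force), a uniform acceleration ramp (force = rho a V), and Newtonian
# Poiseuille flow (axial pressure gradient -4 mu v_max / R^2, bulk
# dissipation 2 pi mu v_max^2 L).

library(lvflow)
dir.create("results", showWarnings = FALSE)
newt <- rheology_params(model = "newtonian", newtonian_mu = 0.0035)

rows <- list()

rr <- make_analytic_field("rigid_rotation", omega = 10, radius = 18)
rows$rigid_rotation_dissipation_w <- c(
  computed = unname(viscous_loss_rate(rr$dataset, 1, newt)["global"]), truth = 0)

ua <- make_analytic_field("uniform_acceleration", dim = c(25, 25, 20),
                          spacing = c(2, 2, 2), n_frames = 6, rr_interval = 1)
b <- pressure_gradient_field(ua$dataset, 3, newt)
fr <- build_frame(ua$dataset$landmarks[[3]])
rows$uniform_acceleration_hdf_n <- c(
  computed = sqrt(sum(hemodynamic_force(b, ua$dataset$spacing, fr, 100)$vector^2)),
  truth = sqrt(sum(ua$truth$hdf_n[3, ]^2)))

po <- make_analytic_field("poiseuille", dim = c(24, 24, 40), spacing = c(1, 1, 2),
                          v_max = 1, radius = 10, mu = 0.0035, n_frames = 3)
bp <- pressure_gradient_field(po$dataset, 2, newt)
g <- velocity_gradient(po$dataset, 2)
core <- bp$mask & !g$lowconf
rows$poiseuille_axial_gradient_pa_m <- c(
  computed = mean(bp$b[, , , 3][core]), truth = po$truth$pressure_gradient[3])
rows$poiseuille_dissipation_w <- c(
  computed = unname(viscous_loss_rate(po$dataset, 2, newt)["global"]),
  truth = po$truth$dissipation_w[1])

tab <- data.frame(quantity = names(rows), do.call(rbind, rows), row.names = NULL)
tab$rel_error <- ifelse(tab$truth != 0, abs(tab$computed - tab$truth) / abs(tab$truth), NA)
write.csv(tab, "results/analytic_oracles.csv", row.names = FALSE)
print(tab, digits = 5)
cat("wrote results/analytic_oracles.csv\n")
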