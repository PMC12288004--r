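# Integrators, constraints, thermostat and stability diagnostics.

two_atom_bond_system <- function(k = 100, r0 = 1.0, mass = 12) {
  build_system(data.frame(element = c("C", "C"), mass = mass, charge = 0),
               bonds = data.frame(i = 0, j = 1, k = k, r0 = r0))
}

test_that("zero forces give exact free flight", {
  s <- build_system(data.frame(element = c("C", "C"), mass = 12, charge = 0))
  v <- rbind(c(0.01, -0.02, 0.005), c(-0.01, 0.02, -0.005))
  fr <- make_frame(rbind(c(0, 0, 0), c(5, 0, 0)), v)
  fr1 <- velocity_verlet_step(s, fr, dt = 2)
  expect_equal(fr1$coords, fr$coords + 2 * v, tolerance = 1e-14)
  expect_equal(fr1$time, 2)
})

test_that("harmonic diatomic oscillates at its closed-form period", {
  k <- 100; mass <- 12; mu <- mass / 2
  period <- 2 * pi * sqrt(mu / (k * 4.184e-4))     # fs, via unit conversion
  s <- two_atom_bond_system(k = k, mass = mass)
  fr <- make_frame(rbind(c(0, 0, 0), c(1.1, 0, 0)))
  out <- run_simulation(s, fr, simulation_plan("NVE", dt = 0.1,
                                               n_steps = 4000L,
                                               report_interval = 1L))
  r <- vapply(out$trajectory$frames,
              function(f) f$coords[2, 1] - f$coords[1, 1], numeric(1))
  # period from spacing of maxima of the bond length
  pk <- which(diff(sign(diff(r))) == -2) + 1L
  est <- mean(diff(pk)) * 0.1
  expect_lt(abs(est - period) / period, 0.01)
})

test_that("velocity Verlet is time reversible", {
  ms <- mixed_test_system()
  fr <- ms$frame
  fr$velocities <- maxwell_boltzmann_velocities(ms$system, 50, seed = 8)
  f <- fr
  for (i in 1:25) f <- velocity_verlet_step(ms$system, f, dt = 0.5)
  f$velocities <- -f$velocities
  for (i in 1:25) f <- velocity_verlet_step(ms$system, f, dt = 0.5)
  expect_lt(max(abs(f$coords - fr$coords)), 1e-10)
})

test_that("Langevin with zero friction reduces to velocity Verlet", {
  ms <- mixed_test_system()
  fr <- ms$frame
  fr$velocities <- maxwell_boltzmann_velocities(ms$system, 100, seed = 4)
  a <- velocity_verlet_step(ms$system, fr, dt = 0.5)
  b <- langevin_step(ms$system, fr, dt = 0.5, temperature = 300, friction = 0)
  expect_equal(a$coords, b$coords, tolerance = 1e-14)
  expect_equal(a$velocities, b$velocities, tolerance = 1e-14)
})

test_that("identical seeds give bitwise-identical trajectories", {
  ss <- toy_droplet(4, 6, seed = 3)
  fr <- ss$frame
  fr$velocities <- maxwell_boltzmann_velocities(ss$system, 100, seed = 1)
  plan <- simulation_plan("NVT", dt = 1, n_steps = 50L, temperature = 100,
                          friction = 1, seed = 17, report_interval = 10L)
  o1 <- run_simulation(ss$system, fr, plan)
  o2 <- run_simulation(ss$system, fr, plan)
  expect_identical(o1$trajectory$frames[[6]]$coords,
                   o2$trajectory$frames[[6]]$coords)
})

test_that("SHAKE restores constrained bonds and is a fixed point", {
  s <- build_system(data.frame(element = c("O", "H"),
                               mass = c(15.999, 1.008), charge = 0),
                    bonds = data.frame(i = 0, j = 1, k = 450, r0 = 0.9572),
                    constraints = data.frame(i = 0, j = 1, d0 = 0.9572))
  x0 <- rbind(c(0, 0, 0), c(0.9572, 0, 0))
  # stretched by 0.01 A
  xs <- rbind(c(0, 0, 0), c(0.9672, 0, 0))
  out <- apply_shake(s, make_frame(x0), make_frame(xs), tolerance = 1e-10)
  d <- sqrt(sum((out$coords[1, ] - out$coords[2, ])^2))
  expect_lt(abs(d - 0.9572), 1e-8)
  # already satisfied -> unchanged
  out2 <- apply_shake(s, make_frame(x0), make_frame(x0), tolerance = 1e-10)
  expect_equal(out2$coords, x0, tolerance = 1e-12)
  # no constraints -> identity
  s2 <- two_atom_bond_system()
  fr <- make_frame(xs)
  expect_identical(apply_shake(s2, make_frame(x0), fr), fr)
})

test_that("constrained dynamics keeps bond lengths within tolerance", {
  bath <- make_solvent_bath(5, box_edge = 8, seed = 6, periodic = FALSE)
  sys <- build_system(bath$atoms, bonds = bath$bonds, angles = bath$angles)
  fr <- make_frame(bath$coords)
  fr$velocities <- maxwell_boltzmann_velocities(sys, 150, seed = 2)
  plan <- simulation_plan("NVT", dt = 2, n_steps = 200L, temperature = 150,
                          friction = 1, shake = TRUE, shake_tol = 1e-8,
                          report_interval = 20L, seed = 3)
  out <- run_simulation(sys, fr, plan)
  cons <- shake_h_constraints(sys)
  for (f in out$trajectory$frames[-1]) {
    d <- sqrt(rowSums((f$coords[cons$i + 1, ] - f$coords[cons$j + 1, ])^2))
    expect_lt(max(abs(d - cons$d0)), 1e-6)
  }
})

test_that("NVE conserves linear momentum and energy on a droplet", {
  ss <- toy_droplet(4, 8, seed = 21)
  fre <- prepare_equilibrated_frame(ss$system, ss$frame, temperature = 100,
                                    n_equil = 500L, seed = 2)
  out <- run_simulation(ss$system, fre,
                        simulation_plan("NVE", dt = 0.5, n_steps = 3000L,
                                        report_interval = 10L, seed = 3))
  st <- out$stability
  expect_lt(st$com_velocity_norm, 1e-10)
  expect_lt(st$energy_drift, 1e-5)
  # angular momentum conservation (open boundaries)
  L <- function(fr) {
    m <- ss$system$atoms$mass
    xc <- sweep(fr$coords, 2, colSums(fr$coords * m) / sum(m))
    colSums(m * cbind(xc[, 2] * fr$velocities[, 3] - xc[, 3] * fr$velocities[, 2],
                      xc[, 3] * fr$velocities[, 1] - xc[, 1] * fr$velocities[, 3],
                      xc[, 1] * fr$velocities[, 2] - xc[, 2] * fr$velocities[, 1]))
  }
  frs <- out$trajectory$frames
  expect_lt(max(abs(L(frs[[length(frs)]]) - L(frs[[1]]))), 1e-8)
})

test_that("n_steps = 0 returns the initial frame only", {
  ms <- mixed_test_system()
  out <- run_simulation(ms$system, ms$frame,
                        simulation_plan("NVE", dt = 1, n_steps = 0L))
  expect_length(out$trajectory$frames, 1)
  expect_equal(out$trajectory$frames[[1]]$coords, ms$frame$coords)
})

test_that("stability diagnostics reproduce hand-evaluated cases", {
  s <- build_system(data.frame(element = c("C", "C"), mass = c(12, 12), charge = 0))
  x <- rbind(c(0, 0, 0), c(3, 0, 0))
  # rigid uniform translation
  v <- matrix(rep(c(0.01, 0, 0), each = 2), 2, 3)
  tr <- make_trajectory(list(make_frame(x, v, 0), make_frame(x + 0.01, v, 1)))
  st <- stability_diagnostics(tr, s)
  expect_equal(st$translational_energy,
               0.5 * 24 * 0.01^2 * kcal_per_mdunit(), tolerance = 1e-12)
  expect_lt(st$rotational_energy, 1e-12)
  # equal and opposite velocities: COM at rest, kinetic energy positive
  v2 <- rbind(c(0.01, 0, 0), c(-0.01, 0, 0))
  tr2 <- make_trajectory(list(make_frame(x, v2, 0), make_frame(x, v2, 1)))
  st2 <- stability_diagnostics(tr2, s)
  expect_lt(st2$com_velocity_norm, 1e-15)
  expect_lt(st2$translational_energy, 1e-15)
  expect_gt(kinetic_energy(s, make_frame(x, v2)), 0)
  # everything at rest -> all zero
  tr3 <- make_trajectory(list(make_frame(x, time = 0), make_frame(x, time = 1)))
  st3 <- stability_diagnostics(tr3, s)
  expect_equal(st3$com_velocity_norm, 0)
  expect_equal(st3$rotational_energy, 0)
})

test_that("the thermostat samples the Maxwell-Boltzmann kinetic energy", {
  # molecular-system check at modest length; the long 1-D calibration run
  # lives with the acceptance suite
  kT <- kB_kcal() * 200
  s <- langevin_harmonic_1d(50, mass = 12, temperature = 200, friction = 0.1,
                            dt = 1, n_steps = 200000L, seed = 11)
  ke <- 0.5 * 12 * s$v^2 * kcal_per_mdunit()
  w <- window_mean_sem(ke, 0.1)
  expect_lt(abs(w$mean_dvdl - kT / 2), 3 * w$sem)
})
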