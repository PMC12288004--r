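# Energy/force correctness: hand-derived values, finite-difference
# gradients, symmetry properties, coupling endpoint identities.

test_that("hand-derived bond, Coulomb and LJ energies are reproduced", {
  # single harmonic bond k = 100, r0 = 1, r = 1.1 -> 0.5 kcal/mol
  s <- build_system(data.frame(element = c("C", "C"), mass = 12, charge = 0),
                    bonds = data.frame(i = 0, j = 1, k = 100, r0 = 1))
  e <- mm_energy_forces(s, make_frame(rbind(c(0, 0, 0), c(1.1, 0, 0))))$energy
  expect_equal(e, 0.5, tolerance = 1e-12)

  # unit charges at 2 A -> -ke/2
  s <- build_system(data.frame(element = c("Na", "Cl"), mass = c(23, 35.5),
                               charge = c(1, -1)))
  e <- mm_energy_forces(s, make_frame(rbind(c(0, 0, 0), c(2, 0, 0))))$energy
  expect_equal(e, -ke_coulomb() / 2, tolerance = 1e-12)
  expect_equal(e, -166.032, tolerance = 1e-4)

  # LJ pair at r = sigma -> 0
  s <- build_system(data.frame(element = c("Ar", "Ar"), mass = 40, charge = 0,
                               sigma = 3.4, epsilon = 0.238))
  e <- mm_energy_forces(s, make_frame(rbind(c(0, 0, 0), c(3.4, 0, 0))))$energy
  expect_equal(e, 0, tolerance = 1e-10)

  # empty potential -> zero energy and forces
  s <- build_system(data.frame(element = c("C", "C"), mass = 12, charge = 0))
  r <- mm_energy_forces(s, make_frame(rbind(c(0, 0, 0), c(2, 0, 0))))
  expect_equal(r$energy, 0)
  expect_equal(max(abs(r$forces)), 0)
})

test_that("analytic forces match 5-point finite differences for all terms", {
  ms <- mixed_test_system()
  x <- ms$frame$coords
  r <- mm_energy_forces(ms$system, ms$frame)
  g <- fd_gradient(function(xx) mm_energy_forces(ms$system, make_frame(xx))$energy, x)
  expect_lt(rel_force_error(r$forces, g), 1e-6)

  ml <- ml_energy_forces(ms$system, ms$frame)
  g <- fd_gradient(function(xx) ml_energy_forces(ms$system, make_frame(xx))$energy, x)
  expect_lt(rel_force_error(ml$forces, g), 1e-6)

  for (form in c("linear", "softcore")) {
    cp <- coupling_energy_forces(ms$system, ms$frame, 0.4, form)
    g <- fd_gradient(function(xx)
      coupling_energy_forces(ms$system, make_frame(xx), 0.4, form)$energy, x)
    expect_lt(rel_force_error(cp$forces, g), 1e-6)
  }

  # dihedral-bearing surrogate (4+ atom solute includes a 3-fold torsion)
  sol <- make_toy_solute(6, seed = 3)
  set.seed(9)
  xs <- sol$coords + 0.15 * matrix(stats::rnorm(18), 6, 3)
  r <- sol$ml_potential(sol$atoms$element, xs)
  g <- fd_gradient(function(xx) sol$ml_potential(sol$atoms$element, xx)$energy, xs)
  expect_lt(rel_force_error(r$forces, g), 1e-6)
})

test_that("surrogate ML evaluator honours its contract", {
  # diatomic at equilibrium: zero energy, zero force
  pot <- surrogate_ml_potential(list(
    bonds = data.frame(i = 0, j = 1, k = 300, r0 = 1.5),
    elements = c("C", "C")))
  r <- pot(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_equal(r$energy, 0, tolerance = 1e-14)
  expect_lt(max(abs(r$forces)), 1e-10)
  # single scalar energy only
  expect_length(r$energy, 1)
  expect_named(r, c("energy", "forces"))
  # element mismatch rejected
  expect_error(pot(c("C", "N"), rbind(c(0, 0, 0), c(1.5, 0, 0))), "mismatch")
  # displaced diatomic equals the identical MM parametrisation
  s <- build_system(data.frame(element = c("C", "C"), mass = 12, charge = 0),
                    bonds = data.frame(i = 0, j = 1, k = 300, r0 = 1.5))
  x <- rbind(c(0, 0, 0), c(1.73, 0.1, -0.2))
  expect_equal(pot(c("C", "C"), x)$energy,
               mm_energy_forces(s, make_frame(x))$energy, tolerance = 1e-12)
})

test_that("reference energies shift the surrogate by an exact constant", {
  prm <- list(bonds = data.frame(i = 0, j = 1, k = 300, r0 = 1.5),
              elements = c("C", "O"))
  p0 <- surrogate_ml_potential(prm)
  prm$reference_energies <- c(C = -23742.4, O = -47108.9)
  p1 <- surrogate_ml_potential(prm)
  x <- rbind(c(0, 0, 0), c(1.6, 0.2, 0))
  r0 <- p0(c("C", "O"), x); r1 <- p1(c("C", "O"), x)
  expect_equal(r1$energy - r0$energy, -23742.4 - 47108.9)
  expect_equal(r1$forces, r0$forces)
})

test_that("coupling endpoints, linearity and lambda derivative behave", {
  atoms <- data.frame(element = c("Na", "Cl"), mass = c(23, 35.5),
                      charge = c(1, -1))
  mlp <- surrogate_ml_potential(list(elements = "Na"))
  s <- build_system(atoms, ml_selection = 0L, ml_potential = mlp)
  fr <- make_frame(rbind(c(0, 0, 0), c(2, 0, 0)))
  for (form in c("linear", "softcore")) {
    expect_identical(coupling_energy_forces(s, fr, 0, form)$energy, 0)
  }
  e1l <- coupling_energy_forces(s, fr, 1, "linear")$energy
  e1s <- coupling_energy_forces(s, fr, 1, "softcore")$energy
  expect_equal(e1l, -ke_coulomb() / 2, tolerance = 1e-12)
  expect_lt(abs(e1l - e1s), 1e-10)
  expect_equal(coupling_energy_forces(s, fr, 0.5, "linear")$energy, e1l / 2,
               tolerance = 1e-12)
  # dvdl vs central difference in lambda
  for (form in c("linear", "softcore")) {
    for (lam in c(0.2, 0.5, 0.8)) {
      cp <- coupling_energy_forces(s, fr, lam, form)
      h <- 1e-5
      num <- (coupling_energy_forces(s, fr, lam + h, form)$energy -
                coupling_energy_forces(s, fr, lam - h, form)$energy) / (2 * h)
      expect_lt(abs(cp$dvdl - num) / abs(num), 1e-7)
    }
  }
  expect_error(coupling_energy_forces(s, fr, 1.2), "lambda")
})

test_that("Coulomb energies are charge-conjugation invariant", {
  ms <- mixed_test_system()
  atoms2 <- ms$system$atoms
  atoms2$charge <- -atoms2$charge
  mlp <- ms$system$ml_potential
  s2 <- build_system(atoms2, bonds = ms$system$bonds, angles = ms$system$angles,
                     ml_selection = ms$system$ml_idx - 1L, ml_potential = mlp)
  expect_equal(mm_energy_forces(s2, ms$frame)$energy,
               mm_energy_forces(ms$system, ms$frame)$energy, tolerance = 1e-12)
  expect_equal(coupling_energy_forces(s2, ms$frame, 1)$energy,
               coupling_energy_forces(ms$system, ms$frame, 1)$energy,
               tolerance = 1e-12)
})

test_that("energies are invariant under rigid translation (open boundaries)", {
  ms <- mixed_test_system()
  sh <- make_frame(ms$frame$coords + matrix(c(11.3, -7.1, 3.9), 6, 3, byrow = TRUE))
  expect_lt(abs(mm_energy_forces(ms$system, sh)$energy -
                  mm_energy_forces(ms$system, ms$frame)$energy), 1e-9)
  expect_lt(abs(coupling_energy_forces(ms$system, sh, 0.7, "softcore")$energy -
                  coupling_energy_forces(ms$system, ms$frame, 0.7, "softcore")$energy),
            1e-9)
  expect_lt(abs(ml_energy_forces(ms$system, sh)$energy -
                  ml_energy_forces(ms$system, ms$frame)$energy), 1e-9)
})

test_that("the energy report satisfies its summation invariant", {
  ms <- mixed_test_system()
  fr <- ms$frame
  # zero velocities -> zero kinetic energy
  rep0 <- total_energy_report(ms$system, fr, 0.6)
  expect_identical(rep0$E_kinetic, 0)
  scale <- max(abs(unlist(rep0[, 2:6])))
  expect_lt(abs(rep0$E_total - (rep0$E_ML + rep0$E_MM + rep0$E_coupling +
                                  rep0$E_kinetic)) / scale, 1e-10)
  fr$velocities <- matrix(0.01, 6, 3)
  rep1 <- total_energy_report(ms$system, fr, 0.6)
  expect_gt(rep1$E_kinetic, 0)
  expect_equal(rep1$E_kinetic,
               0.5 * sum(ms$system$atoms$mass * 3 * 0.01^2) * kcal_per_mdunit(),
               tolerance = 1e-9)
})

test_that("overlapping nonbonded atoms raise a singularity error", {
  s <- build_system(data.frame(element = c("Na", "Cl"), mass = c(23, 35.5),
                               charge = c(1, -1)))
  expect_error(
    mm_energy_forces(s, make_frame(rbind(c(0, 0, 0), c(1e-8, 0, 0)))),
    "singularity")
})
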