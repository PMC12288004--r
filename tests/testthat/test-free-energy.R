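# TI machinery: quadrature, window statistics, reorganization energy,
# free-energy oracles and their cross-checks.

test_that("trapezoid weights and hand arithmetic are exact", {
  expect_equal(quadrature_weights(c(0, 0.5, 1), "trapezoid"),
               c(0.25, 0.5, 0.25))
  wdf <- data.frame(lambda = c(0, 0.5, 1), mean_dvdl = c(-10, -8, -6),
                    sem = c(0, 0, 0))
  expect_equal(integrate_quadrature(wdf, "trapezoid")$dG, -8)
  # trapezoid is exact for linear integrands on any node set
  lam <- c(0, 0.13, 0.4, 0.75, 1)
  a <- 2.3; b <- -5.1
  wdf <- data.frame(lambda = lam, mean_dvdl = a + b * lam, sem = 0)
  expect_equal(integrate_quadrature(wdf, "trapezoid")$dG, a + b / 2,
               tolerance = 1e-14)
  # uncertainty propagates in quadrature
  wdf$sem <- c(0.1, 0.2, 0.1, 0.2, 0.1)
  q <- integrate_quadrature(wdf, "trapezoid")
  expect_equal(q$sem, sqrt(sum(q$weights^2 * wdf$sem^2)))
})

test_that("Gauss-Legendre rule validates nodes and matches dense trapezoid", {
  gl <- pracma::gaussLegendre(8, 0, 1)
  f <- function(x) exp(-2 * x) * sin(3 * x) + 0.5   # smooth integrand
  wdf_gl <- data.frame(lambda = gl$x, mean_dvdl = f(gl$x), sem = 0)
  q_gl <- integrate_quadrature(wdf_gl, "gauss_legendre")
  lam <- seq(0, 1, length.out = 201)
  wdf_tr <- data.frame(lambda = lam, mean_dvdl = f(lam), sem = 0)
  q_tr <- integrate_quadrature(wdf_tr, "trapezoid")
  expect_lt(abs(q_gl$dG - q_tr$dG), 1e-4)
  # wrong nodes are rejected
  expect_error(integrate_quadrature(
    data.frame(lambda = seq(0, 1, length.out = 8), mean_dvdl = 1, sem = 0),
    "gauss_legendre"), "Gauss-Legendre")
})

test_that("window statistics: constant series, white noise, equilibration", {
  w <- window_mean_sem(rep(3.7, 50))
  expect_equal(w$mean_dvdl, 3.7)
  expect_identical(w$sem, 0)
  set.seed(31)
  z <- stats::rnorm(10000)
  w <- window_mean_sem(z, 0)
  expect_lt(abs(w$sem - 1 / sqrt(10000)) / (1 / sqrt(10000)), 0.2)
  # equilibration_fraction = 0.5 on a length-10 series: mean of last 5
  w <- window_mean_sem(1:10, 0.5)
  expect_equal(w$mean_dvdl, mean(6:10))
  expect_equal(w$n_samples, 5)
  expect_error(window_mean_sem(c(1), 0), "too short")
})

test_that("reorganization energy is a difference of phase means", {
  expect_equal(reorganization_energy(rep(-3, 20), rep(-5, 20))$dG_reorg, 2)
  r <- reorganization_energy(rep(1.5, 10), rep(1.5, 10))
  expect_identical(r$dG_reorg, 0)
  expect_identical(r$sem, 0)
  expect_error(reorganization_energy(numeric(), rep(1, 5)), "non-empty")
})

test_that("the exact oracle reproduces closed-form harmonic free energies", {
  h <- make_harmonic_1d(1, 4, 300)
  kT <- kB_kcal() * 300
  expect_equal(h$dG_exact, 0.5 * kT * log(4), tolerance = 1e-12)
  expect_equal(oracle_exact(h$V0, h$V1, 300), h$dG_exact, tolerance = 1e-6)
  # identical endpoints -> 0; swapping endpoints negates
  expect_equal(oracle_exact(h$V0, h$V0, 300), 0, tolerance = 1e-9)
  expect_equal(oracle_exact(h$V1, h$V0, 300), -h$dG_exact, tolerance = 1e-6)
  # 2-D: independent harmonic pair, dG adds per dimension
  V0 <- function(x, y) 0.5 * (x^2 + y^2)
  V1 <- function(x, y) 0.5 * (4 * x^2 + 4 * y^2)
  expect_equal(oracle_exact(V0, V1, 300, ndim = 2), 2 * h$dG_exact,
               tolerance = 1e-5)
})

test_that("BAR recovers closed-form answers and flags empty sides", {
  kT <- kB_kcal() * 300
  # identical states: all work zero
  b <- oracle_bar(rep(0, 100), rep(0, 100), 300)
  expect_equal(b$dG, 0, tolerance = 1e-10)
  # shifted minima, same stiffness: dG = 0
  set.seed(5)
  k <- 2; d <- 0.6
  x0 <- stats::rnorm(4000, 0, sqrt(kT / k))
  x1 <- stats::rnorm(4000, d, sqrt(kT / k))
  V0 <- function(x) 0.5 * k * x^2; V1 <- function(x) 0.5 * k * (x - d)^2
  b <- oracle_bar(V1(x0) - V0(x0), V0(x1) - V1(x1), 300)
  expect_lt(abs(b$dG), 3 * b$sem + 1e-3)
  # stiffness change: dG = (kT/2) ln(k1/k0)
  x0 <- stats::rnorm(6000, 0, sqrt(kT / 1))
  x1 <- stats::rnorm(6000, 0, sqrt(kT / 4))
  W0 <- function(x) 0.5 * 1 * x^2; W1 <- function(x) 0.5 * 4 * x^2
  b <- oracle_bar(W1(x0) - W0(x0), W0(x1) - W1(x1), 300)
  expect_lt(abs(b$dG - 0.5 * kT * log(4)), 3 * b$sem + 0.01)
  # one-sided exponential averaging still works
  b1 <- oracle_bar(W1(x0) - W0(x0), numeric(), 300)
  expect_lt(abs(b1$dG - 0.5 * kT * log(4)), 0.05)
})

test_that("exact-average TI converges to the oracle as windows grow", {
  h <- make_harmonic_1d(1, 4, 300)
  errs <- vapply(c(6, 11, 21), function(nw) {
    w <- ti_exact_windows(h$V0, h$V1, seq(0, 1, length.out = nw), 300)
    abs(integrate_quadrature(w, "trapezoid")$dG - h$dG_exact)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
  # linear coupling of a bounded perturbation: 21-window TI matches the
  # quadrature-evaluated reference within discretisation error
  V0 <- function(x) 0.5 * x^2
  V1 <- function(x) 0.5 * x^2 + 0.8 * tanh(x)       # bounded perturbation
  ref <- oracle_exact(V0, V1, 300)
  w <- ti_exact_windows(V0, V1, seq(0, 1, length.out = 21), 300)
  expect_lt(abs(integrate_quadrature(w, "trapezoid")$dG - ref), 2e-3)
})

test_that("sampled 1-D TI is antisymmetric under path reversal", {
  fwd <- ti_harmonic_sampled(25, 100, n_steps = 8000L, seed = 3)
  rev <- ti_harmonic_sampled(100, 25, n_steps = 8000L, seed = 4)
  expect_lt(abs(fwd$dG + rev$dG), 3 * sqrt(fwd$sem^2 + rev$sem^2))
})

test_that("lambda protocols validate their grids", {
  expect_error(lambda_protocol(c(0, 0.5, 0.5, 1)), "strictly increasing")
  expect_error(lambda_protocol(c(0.1, 0.5, 1), rule = "trapezoid"), "endpoint")
  p <- lambda_protocol(seq(0, 1, 0.25))
  expect_equal(sum(p$weights), 1)
})

test_that("a lambda = 0 linear window records the unscaled coupling energy", {
  ss <- toy_droplet(4, 6, seed = 9)
  fr <- ss$frame
  fr$velocities <- maxwell_boltzmann_velocities(ss$system, 80, seed = 2)
  prot <- lambda_protocol(c(0, 1), coupling_form = "linear",
                          plan = simulation_plan("NVT", dt = 1, n_steps = 100L,
                                                 temperature = 80, friction = 1,
                                                 report_interval = 10L),
                          equilibration_fraction = 0)
  sm <- sample_window(ss$system, fr, prot, 1, "water", seed = 5)
  e1 <- vapply(sm$trajectory$frames, function(f)
    coupling_energy_forces(ss$system, f, 1, "linear")$energy, numeric(1))
  expect_equal(sm$dvdl, e1, tolerance = 1e-10)
  # determinism: identical seeds give identical series
  sm2 <- sample_window(ss$system, fr, prot, 1, "water", seed = 5)
  expect_identical(sm$dvdl, sm2$dvdl)
})

test_that("zero-coupling solutes give a statistically zero solvation dG", {
  # solute with all charges and LJ zeroed: nothing to couple
  sol <- make_toy_solute(4, seed = 13, charge_scale = 0)
  sol$atoms$sigma <- 0; sol$atoms$epsilon <- 0
  bath <- make_solvent_bath(6, box_edge = 9, seed = 14, periodic = FALSE)
  ss <- solvate_toy_system(sol, bath, clearance = 2.8)
  expect_equal(ss$system$nb$coupling$n_pairs, 0)
  fr <- ss$frame
  fr$velocities <- maxwell_boltzmann_velocities(ss$system, 80, seed = 1)
  prot <- lambda_protocol(c(0, 0.5, 1),
                          plan = simulation_plan("NVT", dt = 1, n_steps = 200L,
                                                 temperature = 80, friction = 1,
                                                 report_interval = 10L),
                          equilibration_fraction = 0.2)
  ti <- solvation_free_energy(ss$system, fr, prot, seed = 3)
  expect_identical(ti$dG_coupling, 0)
  # identical intra-ML dynamics in both phases: reorg is statistical zero
  expect_lt(abs(ti$dG_reorg), 3 * ti$dG_reorg_sem + 0.05)
})
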