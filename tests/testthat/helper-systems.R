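# Shared builders and numeric helpers for the test suite.

# 5-point central finite-difference gradient of a scalar function of an
# n x 3 coordinate matrix.
fd_gradient <- function(efun, x, h = 1e-4) {
  g <- x * 0
  for (a in seq_len(nrow(x))) {
    for (k in 1:3) {
      xp <- x; xm <- x; xp2 <- x; xm2 <- x
      xp[a, k] <- x[a, k] + h;  xm[a, k] <- x[a, k] - h
      xp2[a, k] <- x[a, k] + 2 * h; xm2[a, k] <- x[a, k] - 2 * h
      g[a, k] <- (8 * (efun(xp) - efun(xm)) - (efun(xp2) - efun(xm2))) / (12 * h)
    }
  }
  g
}

rel_force_error <- function(forces, grad) {
  scale <- max(abs(grad), 1e-8)
  max(abs(forces + grad)) / scale
}

# A small mixed system: 3-atom ML chain + 3-atom MM chain with charges,
# LJ, bonds/angles on the MM side and a surrogate on the ML side.
mixed_test_system <- function(seed = 42) {
  set.seed(seed)
  atoms <- data.frame(
    element = c("C", "C", "O", "N", "C", "H"),
    mass = c(12.011, 12.011, 15.999, 14.007, 12.011, 1.008),
    charge = c(0.3, -0.2, -0.1, 0.25, -0.15, -0.1),
    sigma = stats::runif(6, 3, 3.5), epsilon = stats::runif(6, 0.05, 0.2))
  mlp <- surrogate_ml_potential(list(
    bonds = data.frame(i = 0:1, j = 1:2, k = 300, r0 = 1.5),
    angles = data.frame(i = 0, j = 1, k_idx = 2, ktheta = 50, theta0 = 1.9),
    elements = c("C", "C", "O")))
  sys <- build_system(atoms,
                      bonds = data.frame(i = 3:4, j = 4:5, k = 280, r0 = 1.4),
                      angles = data.frame(i = 3, j = 4, k_idx = 5,
                                          ktheta = 40, theta0 = 2.0),
                      ml_selection = 0:2, ml_potential = mlp)
  x <- cbind(seq(0, 7.5, 1.5) + stats::rnorm(6, 0, 0.25),
             stats::rnorm(6, 0, 0.4), stats::rnorm(6, 0, 0.4))
  list(system = sys, frame = make_frame(x))
}

# Solvated toy droplet used by dynamics / TI tests (open boundaries).
toy_droplet <- function(n_solute = 6, n_solvent = 30, seed = 11,
                        flexible = TRUE) {
  sol <- make_toy_solute(n_solute, flexible = flexible, seed = seed)
  bath <- make_solvent_bath(n_solvent, box_edge = 14, seed = seed + 1,
                            periodic = FALSE)
  solvate_toy_system(sol, bath)
}

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", actual, expected, tol))
}
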