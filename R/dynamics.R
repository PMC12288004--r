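#' Simulation plan
#'
#' Describes one molecular-dynamics run. NVE runs use plain velocity
#' Verlet; NVT runs use the BAOAB discretisation of Langevin dynamics.
#' With `shake = TRUE` the system's constraint list (or, when the system
#' carries none, the standard bonds-to-hydrogen list) is enforced each
#' step, which permits the longer 2 fs step; unconstrained runs default to
#' 1 fs.
#'
#' @param ensemble "NVE" or "NVT".
#' @param dt time step, fs.
#' @param n_steps number of integration steps.
#' @param temperature target temperature, K (NVT; also used to draw
#'   initial velocities when requested).
#' @param friction Langevin friction, 1/fs (NVT).
#' @param shake logical; enforce holonomic distance constraints.
#' @param shake_tol SHAKE convergence tolerance, A.
#' @param seed integer seed for the run's random stream.
#' @param report_interval record a frame every this many steps.
#' @return list of class `simulation_plan`.
#' @export
simulation_plan <- function(ensemble = c("NVE", "NVT"), dt = 1, n_steps = 1000L,
                            temperature = 300, friction = 1, shake = FALSE,
                            shake_tol = 1e-8, seed = 1L, report_interval = 10L) {
  ensemble <- match.arg(ensemble)
  if (dt <= 0) stop("dt must be positive")
  if (ensemble == "NVT" && temperature <= 0) stop("NVT requires temperature > 0")
  structure(list(ensemble = ensemble, dt = dt, n_steps = as.integer(n_steps),
                 temperature = temperature, friction = friction, shake = shake,
                 shake_tol = shake_tol, seed = as.integer(seed),
                 report_interval = as.integer(report_interval)),
            class = "simulation_plan")
}

# acceleration (A/fs^2) from forces (kcal/mol/A)
.accel <- function(forces, mass) forces * .KCAL2MDU / mass

#' One velocity Verlet step
#'
#' Symplectic update: half-kick, drift, recompute forces, half-kick. The
#' input frame's forces are recomputed internally; for production loops use
#' [run_simulation()], which carries forces across steps.
#'
#' @param system an `mlmm_system`; @param frame an `mlmm_frame`.
#' @param lambda coupling lambda; @param dt time step, fs.
#' @param form coupling form passed to [coupling_energy_forces()].
#' @return The advanced `mlmm_frame` (time + dt).
#' @export
velocity_verlet_step <- function(system, frame, lambda = 1, dt = 1,
                                 form = "linear") {
  f0 <- .total_forces(system, frame, lambda, form)$forces
  if (any(!is.finite(f0)))
    stop(sprintf("non-finite force at t = %g fs: integration blow-up", frame$time))
  m <- system$atoms$mass
  v <- frame$velocities + 0.5 * dt * .accel(f0, m)
  x <- frame$coords + dt * v
  fr1 <- make_frame(x, v, frame$time + dt)
  f1 <- .total_forces(system, fr1, lambda, form)$forces
  if (any(!is.finite(f1)))
    stop(sprintf("non-finite force at t = %g fs: integration blow-up", fr1$time))
  fr1$velocities <- v + 0.5 * dt * .accel(f1, m)
  fr1
}

#' One BAOAB Langevin step
#'
#' Splitting B(half kick) A(half drift) O(Ornstein-Uhlenbeck velocity
#' refresh) A(half drift) B(half kick). With `friction = 0` the O step is
#' the identity and the update reduces exactly to velocity Verlet. The
#' random stream is R's global RNG: seed it (or use [run_simulation()],
#' which seeds from the plan) for deterministic trajectories.
#'
#' @inheritParams velocity_verlet_step
#' @param temperature bath temperature, K.
#' @param friction friction coefficient, 1/fs.
#' @return The advanced `mlmm_frame`.
#' @export
langevin_step <- function(system, frame, lambda = 1, dt = 1,
                          temperature = 300, friction = 1, form = "linear") {
  m <- system$atoms$mass
  f0 <- .total_forces(system, frame, lambda, form)$forces
  if (any(!is.finite(f0)))
    stop(sprintf("non-finite force at t = %g fs: integration blow-up", frame$time))
  v <- frame$velocities + 0.5 * dt * .accel(f0, m)
  x <- frame$coords + 0.5 * dt * v
  if (friction > 0) {
    c1 <- exp(-friction * dt)
    c2 <- sqrt((.KB * temperature * .KCAL2MDU / m) * (1 - c1^2))
    v <- c1 * v + c2 * matrix(stats::rnorm(length(v)), nrow(v), 3L)
  }
  x <- x + 0.5 * dt * v
  fr1 <- make_frame(x, v, frame$time + dt)
  f1 <- .total_forces(system, fr1, lambda, form)$forces
  if (any(!is.finite(f1)))
    stop(sprintf("non-finite force at t = %g fs: integration blow-up", fr1$time))
  fr1$velocities <- v + 0.5 * dt * .accel(f1, m)
  fr1
}

#' Iterative SHAKE constraint projection
#'
#' Restores every holonomic distance constraint of the system on the
#' post-step coordinates, using the pre-step coordinates to direct the
#' corrections (mass-weighted, as in the original algorithm). Velocities
#' are corrected by the position shift / dt when `dt` is given (RATTLE-like
#' first half).
#'
#' @param system an `mlmm_system` carrying a `constraints` table.
#' @param frame_prev frame before the unconstrained step.
#' @param frame_new frame after the unconstrained step.
#' @param tolerance largest allowed |d - d0| per constraint, A.
#' @param max_iter iteration cap; exceeding it is an error.
#' @param dt when non-NULL, velocities are adjusted by (dx/dt).
#' @return The corrected `mlmm_frame`.
#' @export
apply_shake <- function(system, frame_prev, frame_new, tolerance = 1e-8,
                        max_iter = 500L, dt = NULL) {
  cons <- system$constraints
  if (is.null(cons) || !nrow(cons)) return(frame_new)
  x <- frame_new$coords
  x0 <- frame_prev$coords
  m <- system$atoms$mass
  ii <- cons$i + 1L; jj <- cons$j + 1L; d0 <- cons$d0
  for (iter in seq_len(max_iter)) {
    worst <- 0
    for (c in seq_along(ii)) {
      a <- ii[c]; b <- jj[c]
      d <- x[a, ] - x[b, ]
      diff <- sum(d * d) - d0[c]^2
      err <- abs(diff) / (2 * d0[c])        # ~ |d - d0|
      if (err > worst) worst <- err
      if (err > 0.1 * tolerance) {
        r0 <- x0[a, ] - x0[b, ]
        g <- diff / (2 * sum(d * r0) * (1 / m[a] + 1 / m[b]))
        x[a, ] <- x[a, ] - g * r0 / m[a]
        x[b, ] <- x[b, ] + g * r0 / m[b]
      }
    }
    if (worst < tolerance) break
    if (iter == max_iter)
      stop("SHAKE failed to converge in ", max_iter, " iterations")
  }
  v <- frame_new$velocities
  if (!is.null(dt)) v <- v + (x - frame_new$coords) / dt
  make_frame(x, v, frame_new$time)
}

#' Draw Maxwell-Boltzmann initial velocities
#'
#' Per-component Gaussian velocities at the target temperature with the
#' centre-of-mass velocity removed.
#'
#' @param system an `mlmm_system`.
#' @param temperature K.
#' @param seed integer seed; NULL uses the current RNG state.
#' @return n x 3 velocity matrix, A/fs.
#' @export
maxwell_boltzmann_velocities <- function(system, temperature, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- system$atoms$mass
  sd <- sqrt(.KB * temperature * .KCAL2MDU / m)
  v <- sd * matrix(stats::rnorm(3L * length(m)), length(m), 3L)
  vc <- colSums(v * m) / sum(m)
  sweep(v, 2L, vc, "-")
}

#' Run a molecular-dynamics simulation
#'
#' NVE (velocity Verlet) or NVT (BAOAB Langevin) propagation at a fixed
#' coupling lambda, with optional SHAKE constraints, periodic frame
#' recording with per-frame energy reports, and a stability report over
#' the recorded frames.
#'
#' @param system an `mlmm_system`.
#' @param frame0 initial `mlmm_frame`.
#' @param plan a [simulation_plan()].
#' @param lambda coupling parameter.
#' @param form coupling form ("linear" or "softcore").
#' @return list with `trajectory` (`mlmm_trajectory`, energies attached)
#'   and `stability` (see [stability_diagnostics()]).
#' @export
run_simulation <- function(system, frame0, plan, lambda = 1, form = "linear") {
  stopifnot(inherits(plan, "simulation_plan"))
  set.seed(plan$seed)
  sys <- system
  if (plan$shake && is.null(sys$constraints)) {
    sys$constraints <- shake_h_constraints(sys)
  }
  use_shake <- !is.null(sys$constraints) && (plan$shake || !is.null(system$constraints))
  m <- sys$atoms$mass
  nvt <- plan$ensemble == "NVT"
  x <- frame0$coords; v <- frame0$velocities; t0 <- frame0$time
  fe <- .total_forces(sys, frame0, lambda, form)
  f <- fe$forces
  rec_frames <- list(); rec_energy <- list()
  rec <- function(fr, fe, k) {
    ek <- 0.5 * sum(m * rowSums(fr$velocities^2)) * .MDU
    list(frame = fr,
         energy = data.frame(time_fs = fr$time, E_ML = fe$E_ML, E_MM = fe$E_MM,
                             E_coupling = fe$E_coupling, E_kinetic = ek,
                             E_total = fe$E_pot + ek, lambda = lambda,
                             dvdl = fe$dvdl))
  }
  r0 <- rec(make_frame(x, v, t0), fe, 0L)
  rec_frames[[1L]] <- r0$frame; rec_energy[[1L]] <- r0$energy
  nrec <- 1L
  dt <- plan$dt
  if (nvt) {
    c1 <- exp(-plan$friction * dt)
    c2 <- sqrt((.KB * plan$temperature * .KCAL2MDU / m) * (1 - c1^2))
  }
  for (step in seq_len(plan$n_steps)) {
    xprev <- x
    if (!nvt) {
      v <- v + 0.5 * dt * f * .KCAL2MDU / m
      x <- x + dt * v
    } else {
      v <- v + 0.5 * dt * f * .KCAL2MDU / m
      x <- x + 0.5 * dt * v
      if (plan$friction > 0)
        v <- c1 * v + c2 * matrix(stats::rnorm(length(v)), nrow(v), 3L)
      x <- x + 0.5 * dt * v
    }
    if (use_shake) {
      shk <- apply_shake(sys, make_frame(xprev, v, 0), make_frame(x, v, 0),
                         tolerance = plan$shake_tol, dt = dt)
      x <- shk$coords; v <- shk$velocities
    }
    fr <- make_frame(x, v, t0 + step * dt)
    fe <- .total_forces(sys, fr, lambda, form)
    if (any(!is.finite(fe$forces)))
      stop("non-finite force at step ", step, ": integration blow-up")
    f <- fe$forces
    v <- v + 0.5 * dt * f * .KCAL2MDU / m
    if (use_shake) {
      # remove velocity components along constraints (RATTLE projection)
      v <- .rattle_velocities(sys, x, v)
    }
    if (step %% plan$report_interval == 0L || step == plan$n_steps) {
      fr$velocities <- v
      nrec <- nrec + 1L
      r <- rec(fr, fe, step)
      rec_frames[[nrec]] <- r$frame; rec_energy[[nrec]] <- r$energy
    }
  }
  energies <- do.call(rbind, rec_energy)
  traj <- make_trajectory(rec_frames, energies)
  stab <- if (length(rec_frames) >= 2L) stability_diagnostics(traj, system) else NULL
  list(trajectory = traj, stability = stab)
}

.rattle_velocities <- function(system, x, v, tol = 1e-10, max_iter = 100L) {
  cons <- system$constraints
  m <- system$atoms$mass
  ii <- cons$i + 1L; jj <- cons$j + 1L
  for (iter in seq_len(max_iter)) {
    worst <- 0
    for (c in seq_along(ii)) {
      a <- ii[c]; b <- jj[c]
      d <- x[a, ] - x[b, ]
      rv <- sum(d * (v[a, ] - v[b, ]))
      if (abs(rv) > worst) worst <- abs(rv)
      kfac <- rv / (sum(d * d) * (1 / m[a] + 1 / m[b]))
      v[a, ] <- v[a, ] - kfac * d / m[a]
      v[b, ] <- v[b, ] + kfac * d / m[b]
    }
    if (worst < tol) break
  }
  v
}

#' Stability diagnostics for a trajectory
#'
#' The robustness metrics used to validate NVE runs:
#' * `energy_drift` — secular drift of the total energy, measured as
#'   |least-squares slope of E(t)| x run length / |mean E|. The regression
#'   separates true drift from the bounded symplectic fluctuation, which is
#'   reported separately as `energy_std`.
#' * `energy_std` — standard deviation of the reported total energy,
#'   kcal/mol (the quantity that shrinks as dt^2 for velocity Verlet).
#' * `com_velocity_norm` — |total momentum| / total mass over recorded
#'   frames (maximum), A/fs.
#' * `translational_energy` — mean (1/2) M |v_COM|^2, kcal/mol.
#' * `rotational_energy` — mean (1/2) omega' I omega from the angular
#'   momentum about the centre of mass, kcal/mol.
#'
#' @param traj an `mlmm_trajectory` whose frames carry velocities; energy
#'   table attached by [run_simulation()] is used when present, otherwise
#'   recomputation is attempted from the system.
#' @param system the `mlmm_system` the trajectory belongs to.
#' @return list of class `stability_report`.
#' @export
stability_diagnostics <- function(traj, system) {
  frames <- traj$frames
  if (length(frames) < 2L) stop("need at least two frames with velocities")
  m <- system$atoms$mass; M <- sum(m)
  com_v <- t(vapply(frames, function(fr) colSums(fr$velocities * m) / M, numeric(3)))
  com_speed <- sqrt(rowSums(com_v^2))
  etrans <- 0.5 * M * rowSums(com_v^2) * .MDU
  erot <- vapply(frames, function(fr) {
    xc <- sweep(fr$coords, 2L, colSums(fr$coords * m) / M, "-")
    vc <- sweep(fr$velocities, 2L, colSums(fr$velocities * m) / M, "-")
    L <- colSums(m * cbind(xc[, 2] * vc[, 3] - xc[, 3] * vc[, 2],
                           xc[, 3] * vc[, 1] - xc[, 1] * vc[, 3],
                           xc[, 1] * vc[, 2] - xc[, 2] * vc[, 1]))
    r2 <- rowSums(xc * xc)
    I <- -t(xc * m) %*% xc
    diag(I) <- diag(I) + sum(m * r2)
    # pseudo-inverse: linear molecules have a singular inertia tensor
    ei <- eigen(I, symmetric = TRUE)
    keep <- ei$values > 1e-10 * max(ei$values, 1e-300)
    if (!any(keep)) return(0)
    omega <- ei$vectors[, keep, drop = FALSE] %*%
      ((t(ei$vectors[, keep, drop = FALSE]) %*% L) / ei$values[keep])
    0.5 * sum(omega * L) * .MDU
  }, numeric(1))
  en <- traj$energies
  if (!is.null(en)) {
    E <- en$E_total; tt <- en$time_fs
  } else {
    E <- vapply(seq_along(frames), function(k)
      total_energy_report(system, frames[[k]])$E_total, numeric(1))
    tt <- vapply(frames, function(fr) fr$time, numeric(1))
  }
  span <- max(tt) - min(tt)
  slope <- if (span > 0 && length(E) > 2L) unname(stats::coef(stats::lm(E ~ tt))[2L]) else 0
  denom <- abs(mean(E))
  drift <- if (denom > 0) abs(slope) * span / denom else abs(slope) * span
  structure(list(energy_drift = drift,
                 energy_std = stats::sd(E),
                 energy_max_excursion = max(abs(E - mean(E))),
                 com_velocity_norm = max(com_speed),
                 translational_energy = mean(etrans),
                 rotational_energy = mean(pmax(erot, 0))),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(paste0("stability report:\n  energy drift (relative): %.3e\n",
                     "  energy std: %.4g kcal/mol\n  COM speed (max): %.3e A/fs\n",
                     "  translational energy: %.4g kcal/mol\n",
                     "  rotational energy: %.4g kcal/mol\n"),
              x$energy_drift, x$energy_std, x$com_velocity_norm,
              x$translational_energy, x$rotational_energy))
  invisible(x)
}

#' Reference 1-D Langevin oscillator
#'
#' BAOAB propagation of a single particle in a harmonic well
#' V(x) = k/2 (x - x0)^2, used as the thermostat's calibration system
#' (equipartition checks) and as the sampler for one-dimensional
#' free-energy oracles. Runs as a tight scalar loop.
#'
#' @param k stiffness, kcal/mol/A^2; @param mass amu; @param x0 well
#'   centre, A.
#' @param temperature K; @param friction 1/fs; @param dt fs.
#' @param n_steps steps; @param seed integer seed.
#' @param x_init,v_init initial condition.
#' @param thin record every `thin`-th step.
#' @return list with vectors `x` (A) and `v` (A/fs) of recorded states.
#' @export
langevin_harmonic_1d <- function(k, mass = 12, x0 = 0, temperature = 300,
                                 friction = 1, dt = 1, n_steps = 10000L,
                                 seed = 1L, x_init = x0, v_init = 0, thin = 1L) {
  set.seed(as.integer(seed))
  kc <- k * .KCAL2MDU              # amu/fs^2
  c1 <- exp(-friction * dt)
  c2 <- sqrt((.KB * temperature * .KCAL2MDU / mass) * (1 - c1^2))
  n_steps <- as.integer(n_steps); thin <- as.integer(thin)
  nrec <- n_steps %/% thin
  xs <- numeric(nrec); vs <- numeric(nrec)
  x <- x_init; v <- v_init
  f <- -kc * (x - x0)
  noise <- stats::rnorm(n_steps)
  r <- 0L
  for (s in seq_len(n_steps)) {
    v <- v + 0.5 * dt * f / mass
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * noise[s]
    x <- x + 0.5 * dt * v
    f <- -kc * (x - x0)
    v <- v + 0.5 * dt * f / mass
    if (s %% thin == 0L) { r <- r + 1L; xs[r] <- x; vs[r] <- v }
  }
  list(x = xs, v = vs)
}

#' Local energy minimisation
#'
#' L-BFGS minimisation of the total potential energy at fixed lambda,
#' using the analytic forces. Used to relax packed starting structures
#' before dynamics.
#'
#' @param system an `mlmm_system`; @param frame starting `mlmm_frame`.
#' @param lambda,form coupling state during minimisation.
#' @param maxit iteration cap.
#' @return The relaxed `mlmm_frame` (velocities preserved), with the
#'   final potential energy in attribute `"energy"`.
#' @export
minimize_energy <- function(system, frame, lambda = 1, form = "linear",
                            maxit = 500L) {
  n <- n_atoms(system)
  fn <- function(p) .total_forces(system,
                                  make_frame(matrix(p, n, 3L)), lambda, form)$E_pot
  gr <- function(p) -as.vector(.total_forces(system,
                                             make_frame(matrix(p, n, 3L)), lambda, form)$forces)
  opt <- stats::optim(as.vector(frame$coords), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e4))
  out <- make_frame(matrix(opt$par, n, 3L), frame$velocities, frame$time)
  attr(out, "energy") <- opt$value
  out
}

#' Remove centre-of-mass motion from a frame
#'
#' Subtracts the mass-weighted mean velocity, zeroing the total linear
#' momentum. Standard before NVE production (thermostatted equilibration
#' does not conserve momentum).
#'
#' @param system an `mlmm_system`; @param frame an `mlmm_frame`.
#' @return The frame with total momentum zero.
#' @export
remove_com_motion <- function(system, frame) {
  m <- system$atoms$mass
  vc <- colSums(frame$velocities * m) / sum(m)
  frame$velocities <- sweep(frame$velocities, 2L, vc, "-")
  frame
}

#' Prepare an equilibrated starting frame
#'
#' The standard pre-production protocol: local energy minimisation,
#' Maxwell-Boltzmann velocities at the target temperature, a short
#' thermostatted equilibration, and removal of centre-of-mass motion
#' (the Langevin thermostat does not conserve momentum).
#'
#' @param system an `mlmm_system`; @param frame starting `mlmm_frame`.
#' @param temperature K.
#' @param n_equil equilibration steps.
#' @param dt equilibration time step, fs.
#' @param friction 1/fs.
#' @param lambda,form coupling state.
#' @param seed integer seed.
#' @return An equilibrated `mlmm_frame` with zero total momentum.
#' @export
prepare_equilibrated_frame <- function(system, frame, temperature = 100,
                                       n_equil = 3000L, dt = 0.5, friction = 0.5,
                                       lambda = 1, form = "linear", seed = 1L) {
  fr <- minimize_energy(system, frame, lambda, form)
  fr$velocities <- maxwell_boltzmann_velocities(system, temperature,
                                                seed = seed)
  eq <- run_simulation(system, fr,
                       simulation_plan("NVT", dt = dt, n_steps = n_equil,
                                       temperature = temperature,
                                       friction = friction, seed = seed,
                                       report_interval = as.integer(n_equil)),
                       lambda = lambda, form = form)
  fr <- eq$trajectory$frames[[length(eq$trajectory$frames)]]
  fr$time <- 0
  remove_com_motion(system, fr)
}
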