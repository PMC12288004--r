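# Vectorised energy/force kernels shared by the MM force field, the
# surrogate ML potential and the region-region coupling. All kernels take
# an n x 3 coordinate matrix and return list(energy, forces) in kcal/mol
# and kcal/mol/A; forces are the exact negative analytic gradient.

.min_image <- function(dr, box) {
  if (is.null(box)) return(dr)
  for (k in 1:3) dr[, k] <- dr[, k] - box[k] * round(dr[, k] / box[k])
  dr
}

.scatter3 <- function(n, idx_list, f_list) {
  # accumulate per-term force contributions f_list[[r]] (m x 3) onto atoms
  # idx_list[[r]] (length m, 1-based)
  F <- matrix(0, n, 3L)
  for (r in seq_along(idx_list)) {
    ii <- idx_list[[r]]
    if (!length(ii)) next
    for (k in 1:3) {
      s <- rowsum(f_list[[r]][, k], group = ii, reorder = FALSE)
      F[as.integer(rownames(s)), k] <- F[as.integer(rownames(s)), k] + s[, 1L]
    }
  }
  F
}

.bond_ef <- function(coords, bonds, box) {
  n <- nrow(coords)
  if (is.null(bonds) || !nrow(bonds))
    return(list(energy = 0, forces = matrix(0, n, 3L)))
  ii <- bonds$i + 1L; jj <- bonds$j + 1L
  dr <- .min_image(coords[ii, , drop = FALSE] - coords[jj, , drop = FALSE], box)
  r <- sqrt(rowSums(dr * dr))
  dE <- bonds$k * (r - bonds$r0)           # dE/dr
  e <- sum(0.5 * bonds$k * (r - bonds$r0)^2)
  fi <- -(dE / r) * dr                     # force on i
  list(energy = e, forces = .scatter3(n, list(ii, jj), list(fi, -fi)))
}

.angle_ef <- function(coords, angles, box) {
  n <- nrow(coords)
  if (is.null(angles) || !nrow(angles))
    return(list(energy = 0, forces = matrix(0, n, 3L)))
  ii <- angles$i + 1L; jj <- angles$j + 1L; kk <- angles$k_idx + 1L
  a <- .min_image(coords[ii, , drop = FALSE] - coords[jj, , drop = FALSE], box)
  b <- .min_image(coords[kk, , drop = FALSE] - coords[jj, , drop = FALSE], box)
  la <- sqrt(rowSums(a * a)); lb <- sqrt(rowSums(b * b))
  ct <- rowSums(a * b) / (la * lb)
  ct <- pmin(1 - 1e-12, pmax(-1 + 1e-12, ct))
  th <- acos(ct); st <- sqrt(1 - ct * ct)
  dE <- angles$ktheta * (th - angles$theta0)
  e <- sum(0.5 * angles$ktheta * (th - angles$theta0)^2)
  # d theta / d r_i = (ct * a/la - b/lb) / (la * st); symmetric for k
  ahat <- a / la; bhat <- b / lb
  dthi <- (ct * ahat - bhat) / (la * st)
  dthk <- (ct * bhat - ahat) / (lb * st)
  fi <- -dE * dthi; fk <- -dE * dthk
  list(energy = e, forces = .scatter3(n, list(ii, kk, jj), list(fi, fk, -(fi + fk))))
}

.dihedral_ef <- function(coords, dihedrals, box) {
  n <- nrow(coords)
  if (is.null(dihedrals) || !nrow(dihedrals))
    return(list(energy = 0, forces = matrix(0, n, 3L)))
  ii <- dihedrals$i + 1L; jj <- dihedrals$j + 1L
  kk <- dihedrals$k_idx + 1L; ll <- dihedrals$l + 1L
  b1 <- .min_image(coords[jj, , drop = FALSE] - coords[ii, , drop = FALSE], box)
  b2 <- .min_image(coords[kk, , drop = FALSE] - coords[jj, , drop = FALSE], box)
  b3 <- .min_image(coords[ll, , drop = FALSE] - coords[kk, , drop = FALSE], box)
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  l2 <- sqrt(rowSums(b2 * b2))
  phi <- atan2(rowSums(cross(n1, n2) * (b2 / l2)), rowSums(n1 * n2))
  e <- sum(dihedrals$kphi * (1 + cos(dihedrals$n * phi - dihedrals$phase)))
  dE <- -dihedrals$kphi * dihedrals$n * sin(dihedrals$n * phi - dihedrals$phase)
  n1sq <- rowSums(n1 * n1); n2sq <- rowSums(n2 * n2)
  # dphi/dr for the four sites (standard analytic result)
  gi <- -(l2 / n1sq) * n1
  gl <-  (l2 / n2sq) * n2
  pG <- (rowSums(b1 * b2) / (n1sq * l2)) * n1 +
        (rowSums(b3 * b2) / (n2sq * l2)) * n2
  gj <- -gi + pG
  gk <- -pG - gl
  fi <- -dE * gi; fj <- -dE * gj; fk <- -dE * gk; fl <- -dE * gl
  list(energy = e,
       forces = .scatter3(n, list(ii, jj, kk, ll), list(fi, fj, fk, fl)))
}

# Plain (lambda = 1) nonbonded Coulomb + 12-6 LJ over a precomputed pairset.
.nb_ef <- function(coords, ps, box) {
  n <- nrow(coords)
  if (!ps$n_pairs) return(list(energy = 0, forces = matrix(0, n, 3L)))
  dr <- .min_image(coords[ps$i, , drop = FALSE] - coords[ps$j, , drop = FALSE], box)
  r2 <- rowSums(dr * dr)
  if (any(r2 < 1e-12))
    stop("nonbonded singularity: atom pair closer than 1e-6 A")
  r <- sqrt(r2); inv6 <- 1 / (r2 * r2 * r2)
  e <- sum(ps$qq / r) + sum(ps$A * inv6 * inv6 - ps$B * inv6)
  # -dE/dr / r (so force on i = coef * dr)
  coef <- ps$qq / (r2 * r) + (12 * ps$A * inv6 * inv6 - 6 * ps$B * inv6) / r2
  fp <- coef * dr
  F <- as.matrix(ps$scatter %*% fp)
  list(energy = e, forces = F)
}

#' MM-region energy and forces
#'
#' Classical force-field energy of the MM region: harmonic bonds and
#' angles, cosine dihedrals, and intra-MM Lennard-Jones plus Coulomb with
#' 1-2/1-3 exclusions and scaled 1-4 pairs. Atoms in the ML region
#' contribute nothing here.
#'
#' @param system an `mlmm_system`.
#' @param frame an `mlmm_frame` over all atoms of the system.
#' @return list with `energy` (kcal/mol) and `forces` (n x 3, kcal/mol/A).
#' @export
mm_energy_forces <- function(system, frame) {
  x <- frame$coords
  if (nrow(x) != n_atoms(system)) stop("frame/system atom count mismatch")
  b <- .bond_ef(x, system$bonds, system$box)
  a <- .angle_ef(x, system$angles, system$box)
  d <- .dihedral_ef(x, system$dihedrals, system$box)
  nb <- .nb_ef(x, system$nb$mm, system$box)
  list(energy = b$energy + a$energy + d$energy + nb$energy,
       forces = b$forces + a$forces + d$forces + nb$forces)
}

#' Construct a surrogate "ML" potential
#'
#' Folds harmonic bond/angle terms, cosine dihedrals and intramolecular
#' LJ + Coulomb pairs over the ML-region atoms into a single opaque
#' evaluator. The evaluator honours the ML-potential contract: it returns
#' exactly one scalar energy and the matching negative-gradient forces,
#' never an internal bonded/nonbonded decomposition — mirroring how a
#' trained interatomic potential exposes only totals.
#'
#' Trained interatomic potentials report total energies that include the
#' atomic reference (self) energies of their quantum-chemistry training
#' labels, so a small organic molecule evaluates to hundreds of thousands
#' of negative kcal/mol. Supplying `reference_energies` (named kcal/mol
#' per element) reproduces that convention: a configuration-independent
#' offset sum is added to every evaluation. It cancels exactly in all
#' energy differences (reorganization energy, forces, free energies).
#'
#' @param params list with optional elements `bonds`, `angles`,
#'   `dihedrals` (data.frames as in [build_system()], indices local to the
#'   ML region) and `pairs` (data.frame `i`,`j`,`qq`,`A`,`B` with `qq` the
#'   ready Coulomb prefactor ke*qi*qj, kcal.A/mol), plus `elements`
#'   (character vector the evaluator validates against) and optional
#'   `reference_energies` (named numeric, kcal/mol per element symbol).
#' @return A function `(elements, coords) -> list(energy, forces)` of class
#'   `ml_potential`.
#' @export
surrogate_ml_potential <- function(params) {
  params$bonds <- if (!is.null(params$bonds) && NROW(params$bonds)) as.data.frame(params$bonds) else NULL
  params$angles <- if (!is.null(params$angles) && NROW(params$angles)) as.data.frame(params$angles) else NULL
  params$dihedrals <- if (!is.null(params$dihedrals) && NROW(params$dihedrals)) as.data.frame(params$dihedrals) else NULL
  pr <- if (!is.null(params$pairs) && NROW(params$pairs)) as.data.frame(params$pairs) else NULL
  elems <- params$elements
  refE <- params$reference_energies
  force(pr)
  f <- function(elements, coords) {
    coords <- as.matrix(coords)
    if (!is.null(elems)) {
      if (length(elements) != length(elems) || any(elements != elems))
        stop("ML potential: element mismatch with parametrisation")
    }
    nl <- nrow(coords)
    b <- .bond_ef(coords, params$bonds, NULL)
    a <- .angle_ef(coords, params$angles, NULL)
    d <- .dihedral_ef(coords, params$dihedrals, NULL)
    e <- b$energy + a$energy + d$energy
    if (!is.null(refE)) {
      if (any(!(elements %in% names(refE))))
        stop("ML potential: no reference energy for element(s): ",
             paste(setdiff(elements, names(refE)), collapse = ", "))
      e <- e + sum(refE[elements])
    }
    F <- b$forces + a$forces + d$forces
    if (!is.null(pr)) {
      ii <- pr$i + 1L; jj <- pr$j + 1L
      dr <- coords[ii, , drop = FALSE] - coords[jj, , drop = FALSE]
      r2 <- rowSums(dr * dr)
      if (any(r2 < 1e-12)) stop("ML potential: overlapping atoms")
      r <- sqrt(r2); inv6 <- 1 / (r2 * r2 * r2)
      e <- e + sum(pr$qq / r) + sum(pr$A * inv6 * inv6 - pr$B * inv6)
      coef <- pr$qq / (r2 * r) + (12 * pr$A * inv6 * inv6 - 6 * pr$B * inv6) / r2
      fp <- coef * dr
      F <- F + .scatter3(nl, list(ii, jj), list(fp, -fp))
    }
    list(energy = e, forces = F)
  }
  class(f) <- c("ml_potential", "function")
  f
}

#' Evaluate the ML-region energy and forces through the system's
#' ML-potential contract
#'
#' @inheritParams mm_energy_forces
#' @return list `energy` (kcal/mol), `forces` (n x 3 over ALL atoms, zero
#'   outside the ML region).
#' @export
ml_energy_forces <- function(system, frame) {
  n <- n_atoms(system)
  F <- matrix(0, n, 3L)
  if (!length(system$ml_idx)) return(list(energy = 0, forces = F))
  res <- system$ml_potential(system$atoms$element[system$ml_idx],
                             frame$coords[system$ml_idx, , drop = FALSE])
  F[system$ml_idx, ] <- res$forces
  list(energy = res$energy, forces = F)
}

#' Lambda-scaled ML-MM coupling energy, forces and dV/dlambda
#'
#' Mechanical-embedding coupling between the regions: Coulomb plus 12-6 LJ
#' over all ML-MM atom pairs, scaled by the alchemical parameter lambda.
#'
#' Two coupling forms are provided. `linear`: E(lambda) = lambda * E(1),
#' so dV/dlambda = E(1). `softcore` (Beutler-style, alpha = 0.5): the LJ
#' r^6 term is shifted by alpha*(1-lambda)*sigma^6 and the Coulomb
#' distance by alpha*(1-lambda) under a single power-1 lambda prefactor,
#' removing the endpoint singularity when solvent overlaps a decoupled
#' solute. Both forms satisfy E(0) = 0 exactly and agree at lambda = 1.
#'
#' @inheritParams mm_energy_forces
#' @param lambda coupling parameter in [0, 1].
#' @param form `"linear"` or `"softcore"`.
#' @param softcore_alpha softcore shift parameter (dimensionless for LJ,
#'   A^2 for the Coulomb distance shift).
#' @return list `energy` (kcal/mol), `forces` (n x 3), `dvdl` (kcal/mol).
#' @export
coupling_energy_forces <- function(system, frame, lambda = 1,
                                   form = c("linear", "softcore"),
                                   softcore_alpha = 0.5) {
  form <- match.arg(form)
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]")
  ps <- system$nb$coupling
  n <- n_atoms(system)
  zero <- list(energy = 0, forces = matrix(0, n, 3L), dvdl = 0)
  if (!ps$n_pairs) return(zero)
  x <- frame$coords
  dr <- .min_image(x[ps$i, , drop = FALSE] - x[ps$j, , drop = FALSE], system$box)
  r2 <- rowSums(dr * dr)
  if (any(r2 < 1e-12)) stop("nonbonded singularity in coupling pair")

  if (form == "linear") {
    r <- sqrt(r2); inv6 <- 1 / (r2 * r2 * r2)
    e1 <- sum(ps$qq / r) + sum(ps$A * inv6 * inv6 - ps$B * inv6)
    coef <- ps$qq / (r2 * r) + (12 * ps$A * inv6 * inv6 - 6 * ps$B * inv6) / r2
    fp <- (lambda * coef) * dr
    F <- as.matrix(ps$scatter %*% fp)
    return(list(energy = lambda * e1, forces = F, dvdl = e1))
  }

  a <- softcore_alpha
  # Coulomb: lambda * qq / sqrt(r^2 + a(1-lambda))
  sC <- a * (1 - lambda)
  rc <- sqrt(r2 + sC)
  eC <- sum(lambda * ps$qq / rc)
  dvdlC <- sum(ps$qq / rc) + sum(lambda * ps$qq * (a / 2) / rc^3)
  coefC <- lambda * ps$qq / rc^3                     # -dE/dr / r
  # LJ: lambda * (A u^2 - B u), u = 1/(r^6 + a(1-lambda) sigma^6)
  d6 <- a * (1 - lambda) * ps$sig6
  r6 <- r2 * r2 * r2
  u <- 1 / (r6 + d6)
  eL <- sum(lambda * (ps$A * u * u - ps$B * u))
  dvdlL <- sum(ps$A * u * u - ps$B * u) +
    sum(lambda * (2 * ps$A * u - ps$B) * u * u * a * ps$sig6)
  # dE/dr = lambda (2Au - B) * (-u^2) * 6 r^5 ; force coef = -dE/dr / r
  coefL <- lambda * (2 * ps$A * u - ps$B) * u * u * 6 * r6 / r2
  fp <- (coefC + coefL) * dr
  F <- as.matrix(ps$scatter %*% fp)
  list(energy = eC + eL, forces = F, dvdl = dvdlC + dvdlL)
}

#' Kinetic energy of a frame
#' @inheritParams mm_energy_forces
#' @return kcal/mol.
#' @export
kinetic_energy <- function(system, frame) {
  v2 <- rowSums(frame$velocities^2)
  0.5 * sum(system$atoms$mass * v2) * .MDU
}

#' Full energy report at a given lambda
#'
#' Partitions the total energy into ML, MM, coupling and kinetic parts.
#' The invariant E_total = E_ML + E_MM + E_coupling + E_kinetic holds by
#' construction.
#'
#' @inheritParams coupling_energy_forces
#' @return one-row data.frame: `time_fs`, `E_ML`, `E_MM`, `E_coupling`,
#'   `E_kinetic`, `E_total`, `lambda`.
#' @export
total_energy_report <- function(system, frame, lambda = 1,
                                form = c("linear", "softcore")) {
  form <- match.arg(form)
  eml <- ml_energy_forces(system, frame)$energy
  emm <- mm_energy_forces(system, frame)$energy
  ec <- coupling_energy_forces(system, frame, lambda, form)$energy
  ek <- kinetic_energy(system, frame)
  data.frame(time_fs = frame$time, E_ML = eml, E_MM = emm, E_coupling = ec,
             E_kinetic = ek, E_total = eml + emm + ec + ek, lambda = lambda)
}

# Total potential forces at lambda (shared by the integrators).
.total_forces <- function(system, frame, lambda, form = "linear") {
  mm <- mm_energy_forces(system, frame)
  ml <- ml_energy_forces(system, frame)
  cp <- coupling_energy_forces(system, frame, lambda, form)
  list(forces = mm$forces + ml$forces + cp$forces,
       E_pot = mm$energy + ml$energy + cp$energy,
       E_ML = ml$energy, E_MM = mm$energy, E_coupling = cp$energy,
       dvdl = cp$dvdl)
}
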