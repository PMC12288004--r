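# Seeded synthetic fixtures: toy solutes with surrogate ML parameters,
# triatomic/monatomic solvent baths, Gaussian harmonic ensembles with
# known B-factors, and paired 1-D harmonic systems with closed-form
# free-energy differences. Identical spec + seed always reproduces the
# same output.

#' Toy solute (ML region) with surrogate potential
#'
#' A connected chain of `n_atoms` heavy atoms built at the equilibrium
#' geometry of its own surrogate parameters (bond length 1.5 A, angle
#' 109.47 deg, trans dihedrals): harmonic bonds (k = 300 kcal/mol/A^2)
#' and angles (k = 50 kcal/mol/rad^2), soft 3-fold cosine dihedrals
#' (k = 0.5 kcal/mol), and intramolecular LJ + Coulomb over pairs
#' separated by >= 3 bonds. Partial charges are drawn from a seeded
#' Gaussian and recentred so the molecule is exactly neutral. The rigid
#' variant adds an exhaustive pairwise distance-constraint list at the
#' built geometry, freezing every internal coordinate.
#'
#' The surrogate carries per-element atomic reference energies on the
#' scale of quantum-chemical atomic total energies (C -23742, N -34256,
#' O -47109, H -314 kcal/mol, i.e. Hartree-Fock-like atomic values),
#' reproducing the total-energy convention of trained interatomic
#' potentials; the offsets cancel in every energy difference.
#'
#' @param n_atoms chain length (>= 2).
#' @param flexible FALSE returns the rigid (fully constrained) variant.
#' @param seed integer seed.
#' @param charge_scale standard deviation of the drawn partial charges, e.
#' @return list: `atoms` (data.frame with region "ML"), `ml_params`
#'   (for [surrogate_ml_potential()]), `ml_potential`, `coords` (n x 3),
#'   `constraints` (rigid variant, else NULL).
#' @export
make_toy_solute <- function(n_atoms, flexible = TRUE, seed = 1L,
                            charge_scale = 0.15) {
  if (n_atoms < 2L) stop("a toy solute needs at least 2 atoms")
  set.seed(as.integer(seed))
  elpool <- c("C", "N", "O")
  el <- sample(elpool, n_atoms, replace = TRUE)
  mass <- c(C = 12.011, N = 14.007, O = 15.999)[el]
  q <- stats::rnorm(n_atoms, 0, charge_scale)
  q <- q - mean(q)                                  # exact neutrality
  sigma <- stats::runif(n_atoms, 3.0, 3.5)
  eps <- stats::runif(n_atoms, 0.05, 0.15)
  atoms <- data.frame(element = unname(el), mass = unname(mass), charge = q,
                      sigma = sigma, epsilon = eps, region = "ML",
                      stringsAsFactors = FALSE)

  r0 <- 1.5; th0 <- acos(-1 / 3)                    # tetrahedral 109.47 deg
  phi0 <- pi / 3                                    # gauche: minimum of the
                                                    # 3-fold dihedral, and the
                                                    # chain is non-planar so
                                                    # distance constraints can
                                                    # rigidify it
  coords <- matrix(0, n_atoms, 3L)
  if (n_atoms >= 2L) coords[2L, ] <- c(r0, 0, 0)
  if (n_atoms >= 3L)
    coords[3L, ] <- coords[2L, ] + r0 * c(cos(pi - th0), sin(pi - th0), 0)
  if (n_atoms >= 4L) {
    for (a in 4:n_atoms) {
      # NeRF internal-coordinate placement: bond r0, angle th0, dihedral phi0
      b1 <- coords[a - 2L, ] - coords[a - 3L, ]
      b2 <- coords[a - 1L, ] - coords[a - 2L, ]
      bc <- b2 / sqrt(sum(b2^2))
      nv <- c(b1[2] * b2[3] - b1[3] * b2[2],
              b1[3] * b2[1] - b1[1] * b2[3],
              b1[1] * b2[2] - b1[2] * b2[1])
      nv <- nv / sqrt(sum(nv^2))
      mv <- c(nv[2] * bc[3] - nv[3] * bc[2],
              nv[3] * bc[1] - nv[1] * bc[3],
              nv[1] * bc[2] - nv[2] * bc[1])
      d_loc <- r0 * c(-cos(th0), sin(th0) * cos(phi0), sin(th0) * sin(phi0))
      coords[a, ] <- coords[a - 1L, ] +
        d_loc[1] * bc + d_loc[2] * mv + d_loc[3] * nv
    }
  }

  bonds <- data.frame(i = 0:(n_atoms - 2L), j = 1:(n_atoms - 1L),
                      k = 300, r0 = r0)
  angles <- if (n_atoms >= 3L)
    data.frame(i = 0:(n_atoms - 3L), j = 1:(n_atoms - 2L),
               k_idx = 2:(n_atoms - 1L), ktheta = 50, theta0 = th0) else NULL
  dihedrals <- if (n_atoms >= 4L)
    data.frame(i = 0:(n_atoms - 4L), j = 1:(n_atoms - 3L),
               k_idx = 2:(n_atoms - 2L), l = 3:(n_atoms - 1L),
               kphi = 0.5, n = 3, phase = 0) else NULL
  pairs <- NULL
  if (n_atoms >= 5L) {
    cmb <- utils::combn(n_atoms, 2L)
    sep <- cmb[2L, ] - cmb[1L, ]
    keep <- sep >= 4L                               # beyond 1-4
    if (any(keep)) {
      ii <- cmb[1L, keep]; jj <- cmb[2L, keep]
      sg <- 0.5 * (sigma[ii] + sigma[jj]); ep <- sqrt(eps[ii] * eps[jj])
      pairs <- data.frame(i = ii - 1L, j = jj - 1L,
                          qq = ke_coulomb() * q[ii] * q[jj],
                          A = 4 * ep * sg^12, B = 4 * ep * sg^6)
    }
  }
  ml_params <- list(bonds = bonds, angles = angles, dihedrals = dihedrals,
                    pairs = pairs, elements = atoms$element,
                    reference_energies = c(H = -313.8, C = -23742.4,
                                           N = -34256.1, O = -47108.9))
  constraints <- NULL
  if (!flexible) {
    cmb <- utils::combn(n_atoms, 2L)
    d0 <- sqrt(rowSums((coords[cmb[1L, ], , drop = FALSE] -
                          coords[cmb[2L, ], , drop = FALSE])^2))
    constraints <- data.frame(i = cmb[1L, ] - 1L, j = cmb[2L, ] - 1L, d0 = d0)
  }
  list(atoms = atoms, ml_params = ml_params,
       ml_potential = surrogate_ml_potential(ml_params),
       coords = coords, constraints = constraints)
}

#' Solvent bath (MM region)
#'
#' Places `n_molecules` solvent molecules in a cube of edge `box_edge` by
#' rejection sampling with a 1.5 A minimum interatomic distance.
#' `lj_charge_triatomic` is a generic flexible three-site water-like
#' model: O-H bonds 0.9572 A (k = 450 kcal/mol/A^2), H-O-H angle
#' 104.52 deg (k = 55 kcal/mol/rad^2), charges O = -0.834, H = +0.417
#' (each molecule exactly neutral), LJ on the heavy site
#' (sigma = 3.1507 A, epsilon = 0.1521 kcal/mol). `lj_monatomic` is a
#' neutral LJ sphere (argon-like).
#'
#' @param n_molecules molecule count.
#' @param box_edge cube edge, A (also returned as the system box unless
#'   `periodic = FALSE`).
#' @param model "lj_charge_triatomic" or "lj_monatomic".
#' @param seed integer seed.
#' @param periodic attach the box to the fragment (default TRUE).
#' @param max_attempts placement attempts per molecule before failing.
#' @return list: `atoms` (region "MM"), `bonds`, `angles`, `coords`,
#'   `box`.
#' @export
make_solvent_bath <- function(n_molecules, box_edge,
                              model = c("lj_charge_triatomic", "lj_monatomic"),
                              seed = 1L, periodic = TRUE, max_attempts = 5000L) {
  model <- match.arg(model)
  set.seed(as.integer(seed))
  mindist <- 1.5
  placed <- NULL                                    # all placed atom coords
  coords <- NULL; atoms <- NULL; bonds <- NULL; angles <- NULL
  roh <- 0.9572; ang <- 104.52 * pi / 180
  mol_template <- if (model == "lj_charge_triatomic") {
    rbind(c(0, 0, 0),
          c(roh, 0, 0),
          c(roh * cos(ang), roh * sin(ang), 0))
  } else matrix(0, 1L, 3L)
  rand_rot <- function() {
    # uniform random rotation from a normalised quaternion
    qv <- stats::rnorm(4); qv <- qv / sqrt(sum(qv^2))
    a <- qv[1]; b <- qv[2]; cc <- qv[3]; d <- qv[4]
    rbind(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc - a * d), 2 * (b * d + a * cc)),
          c(2 * (b * cc + a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d - a * b)),
          c(2 * (b * d - a * cc), 2 * (cc * d + a * b), a^2 - b^2 - cc^2 + d^2))
  }
  for (mol in seq_len(n_molecules)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      centre <- stats::runif(3, 0, box_edge)
      xyz <- sweep(mol_template %*% t(rand_rot()), 2L, centre, "+")
      if (!is.null(placed)) {
        dmin <- min(vapply(seq_len(nrow(xyz)), function(r) {
          dr <- sweep(placed, 2L, xyz[r, ])
          if (periodic) dr <- .min_image(dr, rep(box_edge, 3L))
          sqrt(min(rowSums(dr * dr)))
        }, numeric(1)))
        if (dmin < mindist) next
      }
      ok <- TRUE
      break
    }
    if (!ok) stop("packing failure: could not place molecule ", mol,
                  " after ", max_attempts, " attempts")
    base0 <- if (is.null(coords)) 0L else nrow(coords)
    coords <- rbind(coords, xyz)
    placed <- coords
    if (model == "lj_charge_triatomic") {
      atoms <- rbind(atoms, data.frame(
        element = c("O", "H", "H"), mass = c(15.999, 1.008, 1.008),
        charge = c(-0.834, 0.417, 0.417),
        sigma = c(3.1507, 0, 0), epsilon = c(0.1521, 0, 0),
        region = "MM", stringsAsFactors = FALSE))
      bonds <- rbind(bonds, data.frame(i = base0, j = base0 + 1:2,
                                       k = 450, r0 = roh))
      angles <- rbind(angles, data.frame(i = base0 + 1L, j = base0,
                                         k_idx = base0 + 2L,
                                         ktheta = 55, theta0 = ang))
    } else {
      atoms <- rbind(atoms, data.frame(
        element = "Ar", mass = 39.948, charge = 0,
        sigma = 3.4, epsilon = 0.238, region = "MM", stringsAsFactors = FALSE))
    }
  }
  list(atoms = atoms, bonds = bonds, angles = angles, coords = coords,
       box = if (periodic) rep(box_edge, 3L) else NULL)
}

#' Combine a toy solute and a solvent bath into one solvated system
#'
#' The solute is centred in the bath (translated to the box centre, or to
#' the bath's centroid for open boundaries); bath molecules any atom of
#' which falls within `clearance` of a solute atom are removed, so the
#' returned system may hold fewer solvent molecules than requested.
#'
#' @param solute result of [make_toy_solute()].
#' @param bath result of [make_solvent_bath()].
#' @param clearance solute-solvent minimum distance, A.
#' @return list `system` (`mlmm_system`), `frame` (`mlmm_frame`).
#' @export
solvate_toy_system <- function(solute, bath, clearance = 2.2) {
  ns <- nrow(solute$atoms)
  centre <- if (!is.null(bath$box)) bath$box / 2 else colMeans(bath$coords)
  scoords <- sweep(solute$coords, 2L, colMeans(solute$coords)) +
    matrix(centre, ns, 3L, byrow = TRUE)
  nat_mol <- if (any(bath$atoms$element == "Ar")) 1L else 3L
  nmol <- nrow(bath$coords) / nat_mol
  keep_mol <- vapply(seq_len(nmol), function(mo) {
    rows <- ((mo - 1L) * nat_mol + 1L):(mo * nat_mol)
    all(vapply(rows, function(r) {
      dr <- sweep(scoords, 2L, bath$coords[r, ])
      if (!is.null(bath$box)) dr <- .min_image(dr, bath$box)
      min(sqrt(rowSums(dr * dr))) >= clearance
    }, logical(1)))
  }, logical(1))
  keep_rows <- which(rep(keep_mol, each = nat_mol))
  remap <- match(seq_len(nrow(bath$coords)), keep_rows)   # old row -> new row
  bcoords <- bath$coords[keep_rows, , drop = FALSE]
  batoms <- bath$atoms[keep_rows, , drop = FALSE]
  keep_bond <- if (!is.null(bath$bonds))
    !is.na(remap[bath$bonds$i + 1L]) & !is.na(remap[bath$bonds$j + 1L]) else NULL
  bonds <- if (!is.null(bath$bonds)) {
    b <- bath$bonds[keep_bond, , drop = FALSE]
    b$i <- remap[b$i + 1L] - 1L + ns; b$j <- remap[b$j + 1L] - 1L + ns; b
  } else NULL
  angles <- if (!is.null(bath$angles)) {
    ka <- !is.na(remap[bath$angles$i + 1L]) & !is.na(remap[bath$angles$j + 1L]) &
      !is.na(remap[bath$angles$k_idx + 1L])
    a <- bath$angles[ka, , drop = FALSE]
    a$i <- remap[a$i + 1L] - 1L + ns; a$j <- remap[a$j + 1L] - 1L + ns
    a$k_idx <- remap[a$k_idx + 1L] - 1L + ns; a
  } else NULL
  atoms <- rbind(solute$atoms[, c("element", "mass", "charge", "sigma",
                                  "epsilon", "region")],
                 batoms[, c("element", "mass", "charge", "sigma",
                            "epsilon", "region")])
  sys <- build_system(atoms, bonds = bonds, angles = angles,
                      ml_selection = 0:(ns - 1L),
                      ml_potential = solute$ml_potential,
                      box = bath$box, constraints = solute$constraints)
  list(system = sys, frame = make_frame(rbind(scoords, bcoords)))
}

#' Harmonic ensemble trajectory with known B-factors
#'
#' Independent isotropic Gaussian displacements about fixed mean
#' positions: per-coordinate variance `per_coordinate_variance`, so the
#' exact B-factor is 8 pi^2 sigma^2 for every atom.
#'
#' @param n_atoms atoms; @param per_coordinate_variance A^2.
#' @param n_frames frames; @param seed integer seed.
#' @param spread length scale of the fixed mean positions, A.
#' @return an `mlmm_trajectory`.
#' @export
make_harmonic_ensemble <- function(n_atoms, per_coordinate_variance, n_frames,
                                   seed = 1L, spread = 10) {
  if (per_coordinate_variance < 0) stop("variance must be >= 0")
  set.seed(as.integer(seed))
  base <- matrix(stats::runif(3L * n_atoms, 0, spread), n_atoms, 3L)
  sd <- sqrt(per_coordinate_variance)
  frames <- lapply(seq_len(n_frames), function(f)
    make_frame(base + sd * matrix(stats::rnorm(3L * n_atoms), n_atoms, 3L),
               time = f - 1))
  make_trajectory(frames)
}

#' Paired 1-D harmonic systems with exact free-energy difference
#'
#' Endpoint potentials V0 = k0/2 x^2 and V1 = k1/2 x^2 share a centre, so
#' dG = (kB T / 2) ln(k1 / k0) exactly.
#'
#' @param k0,k1 stiffnesses (> 0), kcal/mol/A^2.
#' @param temperature K.
#' @return list `V0`, `V1` (functions), `k0`, `k1`, `temperature`,
#'   `dG_exact` (kcal/mol).
#' @export
make_harmonic_1d <- function(k0, k1, temperature = 300) {
  if (k0 <= 0 || k1 <= 0) stop("stiffnesses must be positive")
  force(k0); force(k1)
  list(V0 = function(x) 0.5 * k0 * x^2,
       V1 = function(x) 0.5 * k1 * x^2,
       k0 = k0, k1 = k1, temperature = temperature,
       dG_exact = 0.5 * kB_kcal() * temperature * log(k1 / k0))
}
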