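#' Build an ML/MM system
#'
#' A system is the static description of a simulation: the atom table, the
#' MM-region bonded terms, nonbonded exclusions, an optional orthorhombic
#' box, the ML/MM region partition and the ML potential bound to the ML
#' region. Pair lists and sparse force-scatter operators are precomputed
#' here so that energy/force evaluation is fully vectorised.
#'
#' Atom LJ parameters are stored as the self-pair A (kcal.A^12/mol) and B
#' (kcal.A^6/mol) coefficients of the 12-6 potential. When `sigma` /
#' `epsilon` columns are supplied instead, A = 4 eps sigma^12 and
#' B = 4 eps sigma^6 are formed, and cross pairs use Lorentz-Berthelot
#' combining on the recovered sigma/epsilon.
#'
#' Bonded terms may only involve MM-region atoms: the ML region is
#' described solely by its ML potential, and no covalent bond may span the
#' region boundary (whole-molecule ML regions only; no link atoms).
#' Exclusions are generated from the MM bond graph: 1-2 and 1-3 pairs are
#' excluded, 1-4 pairs are scaled (electrostatics / 1.2, LJ / 2.0, the
#' AMBER convention). No exclusions apply across the region boundary.
#'
#' @param atoms data.frame with columns `element`, `mass` (amu), `charge`
#'   (e), and either `lj_A`,`lj_B` or `sigma` (A), `epsilon` (kcal/mol).
#'   Optional `region` column with values "ML"/"MM" (overridden by
#'   `ml_selection` when given).
#' @param bonds data.frame `i`,`j`,`k`,`r0` (0-based indices, kcal/mol/A^2, A)
#'   or NULL.
#' @param angles data.frame `i`,`j`,`k_idx`,`ktheta`,`theta0` (rad); `j` is
#'   the vertex. NULL allowed.
#' @param dihedrals data.frame `i`,`j`,`k_idx`,`l`,`kphi`,`n`,`phase` (rad).
#' @param ml_selection integer vector of 0-based atom indices forming the
#'   ML region (may be empty).
#' @param ml_potential an evaluator created by [surrogate_ml_potential()]
#'   or any function `(elements, coords) -> list(energy, forces)`; required
#'   when `ml_selection` is non-empty.
#' @param box numeric length-3 orthorhombic edge lengths (A) or NULL for
#'   open boundaries. Minimum-image convention is applied when present.
#' @param constraints data.frame `i`,`j`,`d0` of holonomic distance
#'   constraints (0-based), or NULL. [shake_h_constraints()] builds the
#'   usual bonds-to-hydrogen list.
#' @param scale14_elec,scale14_lj divisors applied to 1-4 pairs.
#' @return An object of class `mlmm_system`.
#' @export
build_system <- function(atoms, bonds = NULL, angles = NULL, dihedrals = NULL,
                         ml_selection = integer(), ml_potential = NULL,
                         box = NULL, constraints = NULL,
                         scale14_elec = 1.2, scale14_lj = 2.0) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (n < 1L) stop("system must contain at least one atom")
  req <- c("element", "mass", "charge")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("all atomic masses must be positive")

  if (!all(c("lj_A", "lj_B") %in% names(atoms))) {
    if (all(c("sigma", "epsilon") %in% names(atoms))) {
      atoms$lj_A <- 4 * atoms$epsilon * atoms$sigma^12
      atoms$lj_B <- 4 * atoms$epsilon * atoms$sigma^6
    } else {
      atoms$lj_A <- 0; atoms$lj_B <- 0
    }
  }
  if (any(atoms$lj_A < 0) || any(atoms$lj_B < 0))
    stop("LJ A/B coefficients must be non-negative")

  ml_selection <- as.integer(ml_selection)
  if (length(ml_selection)) {
    if (any(ml_selection < 0L | ml_selection >= n))
      stop("ml_selection index out of range [0, ", n - 1L, "]")
    if (anyDuplicated(ml_selection)) stop("duplicate indices in ml_selection")
  } else if ("region" %in% names(atoms)) {
    ml_selection <- which(atoms$region == "ML") - 1L
  }
  atoms$region <- "MM"
  atoms$region[ml_selection + 1L] <- "ML"
  ml_idx <- ml_selection + 1L                     # 1-based internally
  mm_idx <- setdiff(seq_len(n), ml_idx)

  if (length(ml_idx) && is.null(ml_potential))
    stop("ml_selection is non-empty but no ml_potential was supplied")

  chk_terms <- function(df, cols, label) {
    if (is.null(df) || nrow(as.data.frame(df)) == 0L) return(NULL)
    df <- as.data.frame(df)
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(label, " table lacks column(s): ", paste(miss, collapse = ", "))
    idx <- as.matrix(df[, intersect(c("i", "j", "k_idx", "l"), cols), drop = FALSE])
    if (any(idx < 0L) || any(idx >= n)) stop(label, " term atom index out of range")
    if (any(apply(idx, 1L, anyDuplicated) > 0L)) stop(label, " term repeats an atom index")
    if (any(idx %in% (ml_idx - 1L)))
      stop("bonded ", label, " term touches an ML-region atom; bonded terms are MM-only")
    df
  }
  bonds     <- chk_terms(bonds, c("i", "j", "k", "r0"), "bond")
  angles    <- chk_terms(angles, c("i", "j", "k_idx", "ktheta", "theta0"), "angle")
  dihedrals <- chk_terms(dihedrals, c("i", "j", "k_idx", "l", "kphi", "n", "phase"), "dihedral")
  if (!is.null(bonds) && any(bonds$k < 0)) stop("bond force constants must be >= 0")
  if (!is.null(angles) && any(angles$ktheta < 0)) stop("angle force constants must be >= 0")

  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("box must be three positive orthorhombic edge lengths")
  }

  excl <- .exclusion_pairs(bonds, n)

  sys <- structure(list(
    atoms = atoms, bonds = bonds, angles = angles, dihedrals = dihedrals,
    box = box, ml_idx = ml_idx, mm_idx = mm_idx,
    ml_potential = ml_potential, constraints = .chk_constraints(constraints, n),
    exclusions = excl$excluded, pairs14 = excl$pairs14,
    scale14_elec = scale14_elec, scale14_lj = scale14_lj), class = "mlmm_system")
  sys$nb <- .build_pairlists(sys)
  sys
}

.chk_constraints <- function(constraints, n) {
  if (is.null(constraints) || nrow(as.data.frame(constraints)) == 0L) return(NULL)
  constraints <- as.data.frame(constraints)
  stopifnot(all(c("i", "j", "d0") %in% names(constraints)))
  if (any(constraints$i < 0L) || any(constraints$j < 0L) ||
      any(constraints$i >= n) || any(constraints$j >= n) ||
      any(constraints$i == constraints$j))
    stop("invalid constraint atom indices")
  if (any(constraints$d0 <= 0)) stop("constraint lengths must be positive")
  constraints
}

# 1-2/1-3 exclusions and 1-4 scaled pairs from the MM bond graph.
# Pairs stored as 1-based (i < j) two-column matrices.
.exclusion_pairs <- function(bonds, n) {
  if (is.null(bonds) || nrow(bonds) == 0L)
    return(list(excluded = matrix(integer(), 0L, 2L), pairs14 = matrix(integer(), 0L, 2L)))
  adj <- vector("list", n)
  bi <- bonds$i + 1L; bj <- bonds$j + 1L
  for (b in seq_along(bi)) {
    adj[[bi[b]]] <- c(adj[[bi[b]]], bj[b])
    adj[[bj[b]]] <- c(adj[[bj[b]]], bi[b])
  }
  p12 <- cbind(pmin(bi, bj), pmax(bi, bj))
  p13 <- NULL; p14 <- NULL
  for (a in seq_len(n)) {
    nb1 <- adj[[a]]
    for (b in nb1) {
      nb2 <- setdiff(adj[[b]], a)
      if (length(nb2)) p13 <- rbind(p13, cbind(pmin(a, nb2), pmax(a, nb2)))
      for (cc in nb2) {
        nb3 <- setdiff(adj[[cc]], c(a, b))
        if (length(nb3)) p14 <- rbind(p14, cbind(pmin(a, nb3), pmax(a, nb3)))
      }
    }
  }
  dedup <- function(m) {
    if (is.null(m) || nrow(m) == 0L) return(matrix(integer(), 0L, 2L))
    m <- m[m[, 1L] != m[, 2L], , drop = FALSE]
    unique(m)
  }
  p12 <- dedup(p12); p13 <- dedup(p13); p14 <- dedup(p14)
  excluded <- unique(rbind(p12, p13))
  key <- function(m) m[, 1L] * (n + 1L) + m[, 2L]
  p14 <- p14[!(key(p14) %in% key(excluded)), , drop = FALSE]
  list(excluded = excluded, pairs14 = p14)
}

# Recover per-atom sigma/epsilon from self-pair A/B (zero where undefined).
.sig_eps <- function(A, B) {
  sig6 <- ifelse(B > 0 & A > 0, A / B, 0)
  eps  <- ifelse(B > 0 & A > 0, B^2 / (4 * A), 0)
  list(sigma = sig6^(1 / 6), eps = eps)
}

# Lorentz-Berthelot cross A/B for index vectors ii, jj (1-based).
.cross_AB <- function(atoms, ii, jj) {
  se <- .sig_eps(atoms$lj_A, atoms$lj_B)
  sig <- 0.5 * (se$sigma[ii] + se$sigma[jj])
  eps <- sqrt(se$eps[ii] * se$eps[jj])
  s6 <- sig^6
  list(A = 4 * eps * s6 * s6, B = 4 * eps * s6)
}

# Precompute intra-MM and ML-MM cross pair lists with prefolded
# Coulomb (ke*qi*qj, 1-4 scaled) and LJ A/B (1-4 scaled) coefficients,
# plus sparse scatter operators mapping per-term forces to atoms.
.build_pairlists <- function(sys) {
  atoms <- sys$atoms; n <- nrow(atoms)
  q <- atoms$charge
  out <- list()

  all_pairs <- function(idx) {
    m <- length(idx)
    if (m < 2L) return(matrix(integer(), 0L, 2L))
    cmb <- utils::combn(idx, 2L)
    cbind(pmin(cmb[1L, ], cmb[2L, ]), pmax(cmb[1L, ], cmb[2L, ]))
  }
  key <- function(m) m[, 1L] * (n + 1L) + m[, 2L]

  mm <- all_pairs(sys$mm_idx)
  if (nrow(mm)) {
    mm <- mm[!(key(mm) %in% key(sys$exclusions)), , drop = FALSE]
    is14 <- key(mm) %in% key(sys$pairs14)
    ab <- .cross_AB(atoms, mm[, 1L], mm[, 2L])
    qq <- .KE * q[mm[, 1L]] * q[mm[, 2L]]
    qq[is14] <- qq[is14] / sys$scale14_elec
    ab$A[is14] <- ab$A[is14] / sys$scale14_lj
    ab$B[is14] <- ab$B[is14] / sys$scale14_lj
    keep <- qq != 0 | ab$A != 0 | ab$B != 0
    out$mm <- .pairset(mm[keep, , drop = FALSE], qq[keep],
                       ab$A[keep], ab$B[keep], n)
  } else out$mm <- .pairset(mm, numeric(), numeric(), numeric(), n)

  if (length(sys$ml_idx) && length(sys$mm_idx)) {
    cross <- cbind(rep(sys$mm_idx, each = length(sys$ml_idx)),
                   rep(sys$ml_idx, times = length(sys$mm_idx)))
    ab <- .cross_AB(atoms, cross[, 1L], cross[, 2L])
    qq <- .KE * q[cross[, 1L]] * q[cross[, 2L]]
    keep <- qq != 0 | ab$A != 0 | ab$B != 0
    out$coupling <- .pairset(cross[keep, , drop = FALSE], qq[keep],
                             ab$A[keep], ab$B[keep], n)
  } else out$coupling <- .pairset(matrix(integer(), 0L, 2L), numeric(), numeric(), numeric(), n)
  out
}

.pairset <- function(pairs, qq, A, B, n) {
  p <- nrow(pairs)
  scat <- if (p) {
    Matrix::sparseMatrix(i = c(pairs[, 1L], pairs[, 2L]),
                         j = c(seq_len(p), seq_len(p)),
                         x = c(rep(1, p), rep(-1, p)), dims = c(n, p))
  } else NULL
  sig6 <- ifelse(B > 0 & A > 0, A / B, 1)  # softcore r^6 shift scale
  list(i = pairs[, 1L], j = pairs[, 2L], qq = qq, A = A, B = B,
       sig6 = sig6, scatter = scat, n_pairs = p)
}

#' Create a frame (coordinates + velocities at a time point)
#'
#' @param coords numeric n x 3 matrix, Angstrom.
#' @param velocities numeric n x 3 matrix, Angstrom/fs (defaults to zero).
#' @param time time stamp, fs.
#' @return An object of class `mlmm_frame`.
#' @export
make_frame <- function(coords, velocities = NULL, time = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  if (is.null(velocities)) velocities <- matrix(0, nrow(coords), 3L)
  velocities <- as.matrix(velocities)
  if (!all(dim(velocities) == dim(coords)))
    stop("velocities must match coords in shape")
  if (any(!is.finite(coords)) || any(!is.finite(velocities)))
    stop("frame contains non-finite values")
  structure(list(coords = coords, velocities = velocities, time = as.numeric(time)),
            class = "mlmm_frame")
}

#' Assemble frames into a trajectory
#'
#' @param frames list of `mlmm_frame` objects with increasing time stamps.
#' @param energies optional data.frame of per-frame energy reports.
#' @return An object of class `mlmm_trajectory`.
#' @export
make_trajectory <- function(frames, energies = NULL) {
  if (!length(frames)) stop("a trajectory needs at least one frame")
  tt <- vapply(frames, function(f) f$time, numeric(1))
  if (is.unsorted(tt, strictly = FALSE)) stop("frame times must be non-decreasing")
  structure(list(frames = frames, energies = energies), class = "mlmm_trajectory")
}

#' @export
print.mlmm_system <- function(x, ...) {
  cat(sprintf("ML/MM system: %d atoms (%d ML, %d MM)\n",
              nrow(x$atoms), length(x$ml_idx), length(x$mm_idx)))
  cat(sprintf("  bonded terms: %d bonds, %d angles, %d dihedrals (MM region)\n",
              NROW(x$bonds), NROW(x$angles), NROW(x$dihedrals)))
  cat(sprintf("  nonbonded pairs: %d intra-MM, %d ML-MM coupling\n",
              x$nb$mm$n_pairs, x$nb$coupling$n_pairs))
  if (!is.null(x$box)) cat(sprintf("  box: %.2f x %.2f x %.2f A\n",
                                   x$box[1], x$box[2], x$box[3]))
  if (!is.null(x$constraints)) cat(sprintf("  constraints: %d\n", nrow(x$constraints)))
  invisible(x)
}

#' @export
print.mlmm_trajectory <- function(x, ...) {
  n <- length(x$frames)
  cat(sprintf("trajectory: %d frame(s), t = %.3f .. %.3f fs, %d atoms\n",
              n, x$frames[[1]]$time, x$frames[[n]]$time, nrow(x$frames[[1]]$coords)))
  invisible(x)
}

#' Number of atoms in a system
#' @param system an `mlmm_system`.
#' @return integer atom count.
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Build the standard SHAKE constraint list: MM-region bonds involving
#' exactly one hydrogen, constrained at their equilibrium lengths.
#' @param system an `mlmm_system`.
#' @return data.frame `i`,`j`,`d0` (0-based) or NULL when no such bonds.
#' @export
shake_h_constraints <- function(system) {
  b <- system$bonds
  if (is.null(b) || !nrow(b)) return(NULL)
  el <- system$atoms$element
  hh <- (el[b$i + 1L] == "H") + (el[b$j + 1L] == "H")
  b <- b[hh == 1L, , drop = FALSE]
  if (!nrow(b)) return(NULL)
  data.frame(i = b$i, j = b$j, d0 = b$r0)
}

#' Extract the gas-phase subsystem: ML-region atoms only, governed solely
#' by the ML potential (no MM terms, no coupling, open boundaries).
#'
#' Constraints wholly inside the ML region are carried over with remapped
#' indices so that a rigid solute stays rigid in the gas phase.
#'
#' @param system an `mlmm_system` with a non-empty ML region.
#' @return An `mlmm_system` whose atoms are all ML.
#' @export
gas_phase_system <- function(system) {
  if (!length(system$ml_idx)) stop("system has no ML region")
  atoms <- system$atoms[system$ml_idx, , drop = FALSE]
  rownames(atoms) <- NULL
  cons <- system$constraints
  if (!is.null(cons)) {
    old0 <- system$ml_idx - 1L
    keep <- cons$i %in% old0 & cons$j %in% old0
    cons <- cons[keep, , drop = FALSE]
    if (nrow(cons)) {
      remap <- match(seq_len(nrow(system$atoms)) - 1L, old0) - 1L
      cons$i <- remap[cons$i + 1L]; cons$j <- remap[cons$j + 1L]
    } else cons <- NULL
  }
  build_system(atoms, ml_selection = seq_len(nrow(atoms)) - 1L,
               ml_potential = system$ml_potential, constraints = cons)
}

#' Restrict a frame to the ML region of a system
#' @param system an `mlmm_system`; @param frame an `mlmm_frame`.
#' @return An `mlmm_frame` over the ML atoms only.
#' @export
ml_region_frame <- function(system, frame) {
  make_frame(frame$coords[system$ml_idx, , drop = FALSE],
             frame$velocities[system$ml_idx, , drop = FALSE], frame$time)
}
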