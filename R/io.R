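#' Read an XYZ coordinate file
#'
#' Standard XYZ: atom count line, comment line, then `element x y z`
#' records. Multi-block files are read as multiple frames.
#'
#' @param path file path.
#' @return list with `elements` (character) and `frames` (list of n x 3
#'   coordinate matrices).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (!length(lines)) stop("empty XYZ file: ", path)
  frames <- list(); elements <- NULL; pos <- 1L; nf <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L)
      stop("XYZ parse error at line ", pos, ": expected atom count, got '",
           lines[pos], "'")
    if (pos + 1L + n > length(lines))
      stop("XYZ parse error at line ", pos, ": ", n,
           " atoms declared but file ends early")
    rec <- lines[(pos + 2L):(pos + 1L + n)]
    tok <- strsplit(trimws(rec), "[[:space:]]+")
    bad <- which(vapply(tok, length, integer(1)) < 4L)
    if (length(bad))
      stop("XYZ parse error at line ", pos + 1L + bad[1L],
           ": need 'element x y z'")
    el <- vapply(tok, `[[`, character(1), 1L)
    xyz <- matrix(suppressWarnings(as.numeric(vapply(tok, function(t) t[2:4],
                                                     character(3)))),
                  ncol = 3L, byrow = TRUE)
    if (any(!is.finite(xyz)))
      stop("XYZ parse error near line ", pos + 2L, ": non-numeric coordinate")
    if (is.null(elements)) elements <- el
    else if (!identical(elements, el))
      stop("XYZ frames disagree in elements at line ", pos)
    nf <- nf + 1L
    frames[[nf]] <- xyz
    pos <- pos + 2L + n
  }
  list(elements = elements, frames = frames)
}

#' Write a trajectory (or single frame) to XYZ or PDB
#'
#' XYZ blocks carry the frame time in the comment line; PDB output writes
#' one MODEL per frame with 1-based serial numbers. Coordinates are
#' printed with three decimals (PDB fixed columns) or six (XYZ), so a
#' read-back matches to that precision.
#'
#' @param traj an `mlmm_trajectory` (or single `mlmm_frame`).
#' @param path output path.
#' @param elements character vector of element symbols.
#' @param format "xyz" or "pdb".
#' @return invisibly, the path.
#' @export
write_trajectory <- function(traj, path, elements, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  if (inherits(traj, "mlmm_frame")) traj <- make_trajectory(list(traj))
  frames <- traj$frames
  if (!length(frames)) stop("refusing to write an empty trajectory")
  n <- nrow(frames[[1L]]$coords)
  if (length(elements) != n) stop("element vector does not match atom count")
  con <- file(path, "w"); on.exit(close(con))
  if (format == "xyz") {
    for (fr in frames) {
      writeLines(as.character(n), con)
      writeLines(sprintf("t= %.6f fs", fr$time), con)
      writeLines(sprintf("%-2s %14.6f %14.6f %14.6f", elements,
                         fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
    }
  } else {
    for (kf in seq_along(frames)) {
      fr <- frames[[kf]]
      writeLines(sprintf("MODEL     %4d", kf), con)
      el <- toupper(elements)
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        seq_len(n), substr(el, 1, 4), "MOL", 1L,
        fr$coords[, 1], fr$coords[, 2], fr$coords[, 3], 1, 0, el), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

#' Read coordinates from a PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()] keeping only what the engine
#' needs: element symbols and coordinates (first model).
#'
#' @param path PDB file path.
#' @return list `elements`, `frames` (single coordinate matrix), as
#'   [read_xyz()].
#' @export
read_pdb_coords <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  el <- trimws(pdb$atom$elesy)
  noel <- !nzchar(el)
  if (any(noel)) el[noel] <- gsub("[0-9]", "", trimws(pdb$atom$elety[noel]))
  el <- paste0(substr(el, 1, 1), tolower(substr(el, 2, 2)))
  nm <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nm), function(k) matrix(pdb$xyz[k, ], ncol = 3L, byrow = TRUE))
  list(elements = el, frames = frames)
}

#' Read a topology file
#'
#' The package's plain-text topology is YAML with the blocks:
#' `atoms` (list of `{element, mass, charge, sigma, epsilon}` or
#' `{..., lj_A, lj_B}`), optional `bonds` (`{i, j, k, r0}`), `angles`
#' (`{i, j, k_idx, ktheta, theta0_deg}`), `dihedrals`
#' (`{i, j, k_idx, l, kphi, n, phase_deg}`), `ml_selection` (0-based
#' indices), `ml_params` (surrogate blocks with the same shapes, indices
#' local to the ML region, plus optional `pairs`), `box` (three edge
#' lengths) and `constraints` (`{i, j, d0}`). Angle-type values given in
#' degrees are converted to radians on load.
#'
#' @param path YAML topology path.
#' @return list of parsed components ready for [build_system()].
#' @export
read_topology <- function(path) {
  top <- yaml::read_yaml(path)
  if (is.null(top$atoms) || !length(top$atoms))
    stop("topology ", path, ": no atoms block")
  as_df <- function(x) {
    if (is.null(x) || !length(x)) return(NULL)
    do.call(rbind, lapply(x, function(rec) as.data.frame(rec)))
  }
  atoms <- as_df(top$atoms)
  deg2rad <- function(df, from, to) {
    if (!is.null(df) && from %in% names(df)) {
      df[[to]] <- df[[from]] * pi / 180
      df[[from]] <- NULL
    }
    df
  }
  angles <- deg2rad(as_df(top$angles), "theta0_deg", "theta0")
  dihedrals <- deg2rad(as_df(top$dihedrals), "phase_deg", "phase")
  mlp <- NULL
  if (!is.null(top$ml_params)) {
    mp <- top$ml_params
    mlp <- list(bonds = as_df(mp$bonds),
                angles = deg2rad(as_df(mp$angles), "theta0_deg", "theta0"),
                dihedrals = deg2rad(as_df(mp$dihedrals), "phase_deg", "phase"),
                pairs = as_df(mp$pairs),
                reference_energies = if (!is.null(mp$reference_energies))
                  unlist(mp$reference_energies) else NULL)
  }
  list(atoms = atoms, bonds = as_df(top$bonds), angles = angles,
       dihedrals = dihedrals, ml_selection = as.integer(top$ml_selection %||% integer()),
       ml_params = mlp, box = if (!is.null(top$box)) as.numeric(top$box) else NULL,
       constraints = as_df(top$constraints))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a topology file
#'
#' Inverse of [read_topology()] (angles written in degrees).
#'
#' @param system an `mlmm_system`.
#' @param path output path.
#' @param ml_params optional surrogate parameter list to embed, as taken
#'   by [surrogate_ml_potential()].
#' @return invisibly, the path.
#' @export
write_topology <- function(system, path, ml_params = NULL) {
  df2list <- function(df) {
    if (is.null(df) || !NROW(df)) return(NULL)
    lapply(seq_len(nrow(df)), function(r) as.list(df[r, , drop = FALSE]))
  }
  rad2deg <- function(df, from, to) {
    if (!is.null(df) && from %in% names(df)) {
      df[[to]] <- df[[from]] * 180 / pi
      df[[from]] <- NULL
    }
    df
  }
  acols <- intersect(c("element", "mass", "charge", "lj_A", "lj_B"),
                     names(system$atoms))
  top <- list(atoms = df2list(system$atoms[, acols, drop = FALSE]),
              bonds = df2list(system$bonds),
              angles = df2list(rad2deg(system$angles, "theta0", "theta0_deg")),
              dihedrals = df2list(rad2deg(system$dihedrals, "phase", "phase_deg")),
              ml_selection = as.integer(system$ml_idx - 1L),
              box = system$box,
              constraints = df2list(system$constraints))
  if (!is.null(ml_params)) {
    top$ml_params <- list(
      bonds = df2list(ml_params$bonds),
      angles = df2list(rad2deg(ml_params$angles, "theta0", "theta0_deg")),
      dihedrals = df2list(rad2deg(ml_params$dihedrals, "phase", "phase_deg")),
      pairs = df2list(ml_params$pairs),
      reference_energies = if (!is.null(ml_params$reference_energies))
        as.list(ml_params$reference_energies) else NULL)
    top$ml_params <- Filter(Negate(is.null), top$ml_params)
  }
  top <- Filter(Negate(is.null), top)
  yaml::write_yaml(top, path)
  invisible(path)
}

#' Load a system from coordinate + topology files
#'
#' @param coord_path PDB or XYZ coordinates (format by extension, or set
#'   `format`).
#' @param topology_path YAML topology (see [read_topology()]).
#' @param format optional "xyz"/"pdb" override.
#' @return list with `system` (`mlmm_system`) and `frame` (`mlmm_frame`).
#' @export
load_system <- function(coord_path, topology_path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.pdb$", coord_path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  crd <- if (format == "pdb") read_pdb_coords(coord_path) else read_xyz(coord_path)
  top <- read_topology(topology_path)
  n_c <- length(crd$elements); n_t <- nrow(top$atoms)
  if (n_c != n_t)
    stop("atom-count mismatch: coordinate file has ", n_c,
         " atoms, topology has ", n_t)
  if (any(crd$elements != top$atoms$element)) {
    k <- which(crd$elements != top$atoms$element)[1L]
    stop("element mismatch at atom ", k - 1L, ": coordinates say '",
         crd$elements[k], "', topology says '", top$atoms$element[k], "'")
  }
  mlpot <- NULL
  if (length(top$ml_selection)) {
    if (is.null(top$ml_params))
      stop("topology declares an ML region but carries no ml_params block")
    mp <- top$ml_params
    mp$elements <- top$atoms$element[top$ml_selection + 1L]
    mlpot <- surrogate_ml_potential(mp)
  }
  sys <- build_system(top$atoms, bonds = top$bonds, angles = top$angles,
                      dihedrals = top$dihedrals, ml_selection = top$ml_selection,
                      ml_potential = mlpot, box = top$box,
                      constraints = top$constraints)
  list(system = sys, frame = make_frame(crd$frames[[1L]]))
}

#' Write an energy table to CSV
#'
#' Header columns: time_fs, E_ML, E_MM, E_coupling, E_kinetic, E_total
#' (plus any extra columns present, e.g. lambda and dvdl).
#'
#' @param energies data.frame as produced by [run_simulation()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_energy_csv <- function(energies, path) {
  lead <- c("time_fs", "E_ML", "E_MM", "E_coupling", "E_kinetic", "E_total")
  ord <- c(intersect(lead, names(energies)), setdiff(names(energies), lead))
  utils::write.csv(energies[, ord, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
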