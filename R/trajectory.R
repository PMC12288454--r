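#' Construct a Trajectory
#'
#' @param atoms data.frame with columns serial, atom_name, residue_index,
#'   residue_name, chain_id and (optionally) domain_label.
#' @param coords numeric array n_frames x n_atoms x 3, Angstrom.
#' @return object of class `Trajectory`.
#' @export
new_trajectory <- function(atoms, coords) {
  need <- c("serial", "atom_name", "residue_index", "residue_name", "chain_id")
  assert_that(all(need %in% names(atoms)),
              paste("atoms must have columns", paste(need, collapse = ", ")))
  assert_that(length(dim(coords)) == 3 && dim(coords)[3] == 3,
              "coords must be an n_frames x n_atoms x 3 array")
  assert_that(dim(coords)[2] == nrow(atoms),
              "coords atom dimension does not match atoms table")
  assert_that(all(is.finite(coords)), "coordinates must be finite")
  if (is.null(atoms$domain_label)) atoms$domain_label <- NA_character_
  structure(list(atoms = atoms, coords = coords), class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", dim(x$coords)[1], "frames x", dim(x$coords)[2], "atoms\n")
  invisible(x)
}

#' @rdname new_trajectory
#' @param traj a Trajectory.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname new_trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

# single frame as an n_atoms x 3 matrix
frame_coords <- function(traj, f) {
  matrix(traj$coords[f, , ], ncol = 3)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, fixed-width ATOM records at standard
#' PDB precision (3 decimals).
#'
#' @param traj a [Trajectory] (or a `StructureModel`, written as one model).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  if (inherits(traj, "StructureModel"))
    traj <- new_trajectory(traj$atoms,
                           array(traj$coords, c(1, nrow(traj$coords), 3)))
  at <- traj$atoms
  name4 <- sprintf(" %-3s", substr(at$atom_name, 1, 3))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    lines <- sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                     at$serial, name4, at$residue_name, at$chain_id,
                     at$residue_index, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0)
    writeLines(c(sprintf("MODEL %8d", f), lines, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory in plain XYZ format
#'
#' @inheritParams write_trajectory_pdb
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- n_atoms(traj)
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    writeLines(c(as.character(n), sprintf("frame %d", f),
                 sprintf("%s %.6f %.6f %.6f", traj$atoms$atom_name,
                         xyz[, 1], xyz[, 2], xyz[, 3])), con)
  }
  invisible(path)
}

#' Read a trajectory
#'
#' Multi-model PDB files are parsed with bio3d; plain XYZ files with a
#' built-in reader; DCD files require a PDB `topology` for atom metadata.
#' Residue numbering is preserved from the source (1-based in files written
#' by this package).
#'
#' @param path input file.
#' @param format "pdb", "xyz" or "dcd".
#' @param topology PDB file with the atom table (required for "dcd").
#' @param domain_map optional data.frame (label, start, end) applied per
#'   chain to annotate `domain_label`.
#' @return a [Trajectory] restricted to C-alpha atoms for PDB/DCD input.
#' @export
read_trajectory <- function(path, format = c("pdb", "xyz", "dcd"),
                            topology = NULL, domain_map = NULL) {
  format <- match.arg(format)
  assert_that(file.exists(path), paste("file not found:", path))
  traj <- switch(format,
                 pdb = read_trajectory_pdb(path),
                 xyz = read_trajectory_xyz(path),
                 dcd = read_trajectory_dcd(path, topology))
  if (!is.null(domain_map)) {
    dm <- validate_domain_map(domain_map, max(traj$atoms$residue_index))
    lab <- character(max(dm$end))
    for (k in seq_len(nrow(dm))) lab[dm$start[k]:dm$end[k]] <- dm$label[k]
    traj$atoms$domain_label <- lab[traj$atoms$residue_index]
  }
  traj
}

read_trajectory_pdb <- function(path) {
  raw <- readLines(path)
  atom_lines <- grepl("^(ATOM  |HETATM)", raw)
  if (!any(atom_lines)) stop("format error: no ATOM records in ", path,
                             call. = FALSE)
  # per-model atom-count consistency, before handing off to bio3d
  model_starts <- grepl("^MODEL", raw)
  if (any(model_starts)) {
    model_id <- cumsum(model_starts)
    counts <- table(model_id[atom_lines])
    if (length(unique(as.integer(counts))) != 1) {
      bad <- names(counts)[which(as.integer(counts) != as.integer(counts)[1])[1]]
      stop("format error: model ", bad, " has ", counts[[bad]],
           " atoms, expected ", as.integer(counts)[1], call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  at <- pdb$atom[sel$atom, ]
  atoms <- data.frame(serial = at$eleno, atom_name = at$elety,
                      residue_index = at$resno, residue_name = at$resid,
                      chain_id = at$chain, stringsAsFactors = FALSE)
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  nf <- nrow(xyz)
  n <- nrow(atoms)
  coords <- array(0, c(nf, n, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  new_trajectory(atoms, coords)
}

read_trajectory_xyz <- function(path) {
  raw <- readLines(path)
  if (length(raw) == 0) stop("format error: empty XYZ file", call. = FALSE)
  pos <- 1L
  frames <- list()
  names_seen <- NULL
  while (pos <= length(raw)) {
    if (!grepl("^\\s*\\d+\\s*$", raw[pos]))
      stop("format error: expected atom count at line ", pos, call. = FALSE)
    n <- as.integer(raw[pos])
    block <- raw[(pos + 2):(pos + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4))
      stop("format error: malformed XYZ coordinate line near line ", pos,
           call. = FALSE)
    nm <- vapply(parts, `[[`, "", 1)
    if (is.null(names_seen)) names_seen <- nm
    else if (!identical(nm, names_seen))
      stop("format error: model ", length(frames) + 1L,
           " atom list differs from model 1", call. = FALSE)
    frames[[length(frames) + 1L]] <-
      t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    pos <- pos + 2L + n
  }
  n <- length(names_seen)
  atoms <- data.frame(serial = seq_len(n), atom_name = names_seen,
                      residue_index = seq_len(n), residue_name = "ALA",
                      chain_id = "A", stringsAsFactors = FALSE)
  coords <- array(0, c(length(frames), n, 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  new_trajectory(atoms, coords)
}

read_trajectory_dcd <- function(path, topology) {
  assert_that(!is.null(topology), "DCD input requires a PDB topology file")
  pdb <- bio3d::read.pdb(topology, verbose = FALSE)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  at <- pdb$atom[sel$atom, ]
  atoms <- data.frame(serial = at$eleno, atom_name = at$elety,
                      residue_index = at$resno, residue_name = at$resid,
                      chain_id = at$chain, stringsAsFactors = FALSE)
  xyz <- xyz[, sel$xyz, drop = FALSE]
  coords <- array(0, c(nrow(xyz), nrow(atoms), 3))
  for (f in seq_len(nrow(xyz)))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  new_trajectory(atoms, coords)
}

# Kabsch: proper rotation R and translation mapping P onto Q (rows = points)
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(R = R, cp = cp, cq = cq)
}

#' Least-squares superposition onto a reference structure
#'
#' Each frame is rigid-body transformed (proper rotation + translation, via
#' the Kabsch singular-value solution with a reflection guard) to minimize
#' the least-squares deviation from the reference over the selected atoms.
#'
#' @param traj a [Trajectory].
#' @param reference a `StructureModel` (or a Trajectory, whose first frame is
#'   used) with the same atom ordering.
#' @param selection integer atom indices used for the fit (default: all).
#' @param iterate if TRUE, re-fit to the mean structure until convergence
#'   instead of the fixed reference.
#' @param max_iter,tol iterated-mean controls.
#' @return superposed [Trajectory] (attribute `superposed = TRUE`).
#' @export
superpose <- function(traj, reference, selection = NULL, iterate = FALSE,
                      max_iter = 10L, tol = 1e-8) {
  assert_that(inherits(traj, "Trajectory"), "traj must be a Trajectory")
  ref_xyz <- if (inherits(reference, "Trajectory")) frame_coords(reference, 1)
             else reference$coords
  assert_that(nrow(ref_xyz) == n_atoms(traj),
              "reference and trajectory atom counts differ")
  sel <- selection %||% seq_len(n_atoms(traj))
  if (length(sel) < 3)
    stop("underdetermined superposition: need at least 3 selected atoms",
         call. = FALSE)
  target <- ref_xyz
  repeat {
    out <- traj$coords
    for (f in seq_len(n_frames(traj))) {
      P <- frame_coords(traj, f)
      fit <- kabsch_fit(P[sel, , drop = FALSE], target[sel, , drop = FALSE])
      out[f, , ] <- sweep(sweep(P, 2, fit$cp) %*% fit$R, 2, fit$cq, "+")
    }
    if (!iterate) break
    new_mean <- apply(out, c(2, 3), mean)
    if (max(abs(new_mean - target)) < tol || (max_iter <- max_iter - 1L) <= 0) {
      traj$coords <- out
      break
    }
    target <- new_mean
    traj$coords <- out
  }
  if (!iterate) traj$coords <- out
  attr(traj, "superposed") <- TRUE
  traj
}

#' RMSD and RMSF stability profiles
#'
#' Per-frame root-mean-square deviation from the reference and per-residue
#' root-mean-square fluctuation about the trajectory mean,
#' `RMSF_i = sqrt(<|r_i - <r_i>|^2>)`, both over the selected atoms. The
#' full frame range is used unless `frames` restricts it (e.g. to discard an
#' equilibration window in real data).
#'
#' @param traj a superposed [Trajectory].
#' @param reference structure used for the RMSD (same atom ordering).
#' @param selection integer atom indices (default: all).
#' @param frames optional integer frame subset.
#' @return object of class `StabilityProfile`: list with `rmsd`
#'   (frame, rmsd) and `rmsf` (chain, resid, rmsf) data.frames, Angstrom.
#' @export
rmsd_rmsf <- function(traj, reference, selection = NULL, frames = NULL) {
  ref_xyz <- if (inherits(reference, "Trajectory")) frame_coords(reference, 1)
             else reference$coords
  sel <- selection %||% seq_len(n_atoms(traj))
  fr <- frames %||% seq_len(n_frames(traj))
  nf <- length(fr)
  rmsd <- numeric(nf)
  for (k in seq_len(nf)) {
    d <- frame_coords(traj, fr[k])[sel, , drop = FALSE] -
      ref_xyz[sel, , drop = FALSE]
    rmsd[k] <- sqrt(mean(rowSums(d^2)))
  }
  sub <- traj$coords[fr, sel, , drop = FALSE]
  mean_xyz <- apply(sub, c(2, 3), mean)
  msf <- numeric(length(sel))
  for (k in seq_len(nf)) {
    d <- matrix(sub[k, , ], ncol = 3) - mean_xyz
    msf <- msf + rowSums(d^2)
  }
  rmsf <- sqrt(msf / nf)
  structure(
    list(rmsd = data.frame(frame = fr, rmsd = rmsd),
         rmsf = data.frame(chain = traj$atoms$chain_id[sel],
                           resid = traj$atoms$residue_index[sel],
                           rmsf = rmsf)),
    class = "StabilityProfile"
  )
}

#' Write a stability profile as TSV files
#'
#' @param profile a [rmsd_rmsf()] result.
#' @param rmsd_path,rmsf_path output paths (NULL to skip either).
#' @export
write_stability_tsv <- function(profile, rmsd_path = NULL, rmsf_path = NULL) {
  if (!is.null(rmsd_path))
    utils::write.table(profile$rmsd, rmsd_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(rmsf_path))
    utils::write.table(profile$rmsf, rmsf_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(NULL)
}
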