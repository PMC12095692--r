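#' Ligand + protein trajectory container
#'
#' Frames of ligand and protein coordinates from a free-ligand-diffusion
#' simulation. Atom metadata is constant across frames; coordinates are a
#' frames x atoms x 3 array in Angstrom.
#'
#' @param atoms Tibble with columns `chain`, `resid`, `resname`, `name`,
#'   `element`, `is_ligand`.
#' @param coords Numeric array `[n_frames, n_atoms, 3]`.
#' @param frame_interval_ps Time between frames in ps (default 100).
#' @return An `lf_trajectory` object.
#' @export
lf_trajectory <- function(atoms, coords, frame_interval_ps = 100) {
  atoms <- as_tibble(atoms)
  stopifnot(all(c("chain", "resid", "resname", "name", "element",
                  "is_ligand") %in% names(atoms)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == nrow(atoms),
            dim(coords)[3] == 3)
  if (any(!is.finite(coords))) abort("coordinates must be finite")
  structure(list(atoms = atoms, coords = coords,
                 frame_interval_ps = frame_interval_ps),
            class = "lf_trajectory")
}

#' @export
print.lf_trajectory <- function(x, ...) {
  cat(sprintf(
    "<lf_trajectory> %d frames, %d atoms (%d ligand), dt %g ps\n",
    n_frames(x), nrow(x$atoms), sum(x$atoms$is_ligand),
    x$frame_interval_ps))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `lf_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

frame_coords <- function(traj, frame) {
  m <- traj$coords[frame, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  m
}

#' Read a multi-model PDB trajectory
#'
#' Reads MODEL/ENDMDL multi-model PDB files (the text interchange format for
#' toy trajectories) via `bio3d::read.pdb` and splits atoms into ligand and
#' protein by residue name.
#'
#' @param path PDB file path.
#' @param ligand_resname Residue name of the ligand (default "LIG").
#' @param frame_interval_ps Frame spacing in ps.
#' @return An `lf_trajectory`.
#' @export
read_trajectory_pdb <- function(path, ligand_resname = "LIG",
                                frame_interval_ps = 100) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  el <- at$elesy
  if (is.null(el) || all(!nzchar(trimws(el))))
    el <- substr(trimws(at$elety), 1, 1)
  atoms <- tibble(
    chain = at$chain, resid = at$resno, resname = trimws(at$resid),
    name = trimws(at$elety), element = normalize_element(el),
    is_ligand = trimws(at$resid) == ligand_resname)
  if (!any(atoms$is_ligand))
    abort(paste0("no atoms with residue name ", ligand_resname))
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nf, nrow(atoms), 3))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  lf_trajectory(atoms, coords, frame_interval_ps)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj An `lf_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    lines <- sprintf(
      "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(a$is_ligand, "HETATM", "ATOM"), seq_len(nrow(a)),
      substr(a$name, 1, 4), substr(a$resname, 1, 3), a$chain, a$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
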