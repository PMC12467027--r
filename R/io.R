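#' Write a trajectory in the plain-text multi-frame XYZ format
#'
#' Format: comment lines start with `#`; a header records the time per
#' frame and atom count; each frame is introduced by `frame <time_ns>`
#' followed by one `x y z` line per atom. The atom table goes to a sidecar
#' TSV (`<path>.atoms.tsv` by default) with columns resid, resname, name,
#' heavy, mass.
#'
#' @param traj an [trajectory()]
#' @param path output file
#' @param atoms_path sidecar atom-table file
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path,
                             atoms_path = paste0(path, ".atoms.tsv")) {
  nf <- n_frames(traj); na <- nrow(traj$atoms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# multi-frame xyz trajectory",
               sprintf("# time_per_frame %.9g", traj$time_per_frame),
               sprintf("# n_atoms %d", na),
               sprintf("# n_frames %d", nf)), con)
  for (f in seq_len(nf)) {
    writeLines(sprintf("frame %.9g", (f - 1) * traj$time_per_frame), con)
    m <- traj$coords[f, , , drop = TRUE]
    dim(m) <- c(na, 3)
    writeLines(sprintf("%.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]), con)
  }
  utils::write.table(traj$atoms, atoms_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path trajectory file
#' @param atoms_path sidecar atom-table file
#' @return an [trajectory()]
#' @export
read_trajectory <- function(path, atoms_path = paste0(path, ".atoms.tsv")) {
  lines <- readLines(path)
  tpf <- 1
  hdr <- grep("^# time_per_frame ", lines, value = TRUE)
  if (length(hdr)) tpf <- as.numeric(sub("^# time_per_frame ", "", hdr[1]))
  lines <- lines[!grepl("^#", lines)]
  starts <- grep("^frame", lines)
  if (length(starts) == 0L) stop("no frames found in ", path)
  na <- (if (length(starts) > 1L) starts[2] else length(lines) + 1L) -
    starts[1] - 1L
  atoms <- utils::read.table(atoms_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (nrow(atoms) != na) stop("atom table does not match frame size")
  nf <- length(starts)
  coords <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) {
    block <- lines[(starts[f] + 1L):(starts[f] + na)]
    m <- matrix(as.numeric(unlist(strsplit(trimws(block), "\\s+"))),
                ncol = 3, byrow = TRUE)
    coords[f, , ] <- m
  }
  trajectory(coords, atoms, time_per_frame = tpf)
}

#' Write receptor-fixture (or any CA-table) coordinates as PDB
#'
#' @param fixture list with `xyz` and `atoms` as returned by
#'   [make_receptor_fixture()]
#' @param path output PDB file
#' @return `path`, invisibly
#' @export
write_receptor_pdb <- function(fixture, path) {
  bio3d::write.pdb(file = path, xyz = as.vector(t(fixture$xyz)),
                   resno = fixture$atoms$resid,
                   resid = fixture$atoms$resname,
                   elety = fixture$atoms$name,
                   chain = rep("A", nrow(fixture$atoms)))
  invisible(path)
}

#' Read receptor coordinates from PDB
#'
#' @param path PDB file
#' @return list with `xyz` and `atoms` in the fixture layout
#' @export
read_receptor_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  list(xyz = xyz,
       atoms = data.frame(resid = pdb$atom$resno,
                          resname = pdb$atom$resid,
                          name = pdb$atom$elety,
                          heavy = pdb$atom$elesy != "H",
                          mass = element_mass(pdb$atom$elesy)))
}

#' Write a ligand as PDB plus a topology sidecar
#'
#' Coordinates go to HETATM records; bonds, atom classes and rotatable
#' dihedrals go to a plain-text sidecar with `atom`, `bond` and
#' `dihedral` records.
#'
#' @param lig an [ligand()]
#' @param pdb_path coordinate file
#' @param top_path topology sidecar (default `<pdb_path>.top`)
#' @return `pdb_path`, invisibly
#' @export
write_ligand <- function(lig, pdb_path,
                         top_path = paste0(pdb_path, ".top")) {
  n <- nrow(lig$atoms)
  bio3d::write.pdb(file = pdb_path, xyz = as.vector(t(lig$xyz)),
                   type = rep("HETATM", n),
                   resno = rep(1L, n), resid = rep("LIG", n),
                   elety = paste0(lig$atoms$element, seq_len(n)),
                   elesy = lig$atoms$element,
                   chain = rep("A", n))
  con <- file(top_path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# ligand topology for '%s'", lig$name),
               "# atom <index> <element> <class> <is_h>",
               "# bond <i> <j>"), con)
  writeLines(sprintf("atom %d %s %s %d", seq_len(n), lig$atoms$element,
                     lig$atoms$class, as.integer(lig$atoms$is_h)), con)
  if (nrow(lig$bonds))
    writeLines(sprintf("bond %d %d", lig$bonds[, 1], lig$bonds[, 2]), con)
  invisible(pdb_path)
}

#' Read a ligand from PDB plus topology sidecar
#'
#' Rotatable dihedrals are re-derived from the bond graph by the standard
#' rule, so only atoms and bonds need to be stored.
#'
#' @param pdb_path coordinate file
#' @param top_path topology sidecar
#' @param name ligand label
#' @return an [ligand()]
#' @export
read_ligand <- function(pdb_path, top_path = paste0(pdb_path, ".top"),
                        name = "ligand") {
  pdb <- bio3d::read.pdb(pdb_path)
  xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  lines <- readLines(top_path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  atom_lines <- grep("^atom ", lines, value = TRUE)
  bond_lines <- grep("^bond ", lines, value = TRUE)
  at <- do.call(rbind, strsplit(atom_lines, "\\s+"))
  bonds <- if (length(bond_lines)) {
    b <- do.call(rbind, strsplit(bond_lines, "\\s+"))
    matrix(as.integer(b[, 2:3]), ncol = 2)
  } else NULL
  ligand(elements = at[, 3], classes = at[, 4], xyz = xyz, bonds = bonds,
         is_h = at[, 5] == "1", name = name)
}

#' Write docked poses as a multi-model PDB plus an LGFE table
#'
#' @param result a [dock()] result
#' @param pdb_path multi-model PDB of the ranked poses
#' @param csv_path CSV with rank, LGFE and COM per pose (NULL to skip)
#' @return `pdb_path`, invisibly
#' @export
write_poses <- function(result, pdb_path, csv_path = NULL) {
  lig <- result$best_pose$ligand
  n <- nrow(lig$atoms)
  con <- file(pdb_path, "w")
  on.exit(close(con))
  for (r in seq_along(result$top_poses)) {
    p <- result$top_poses[[r]]
    writeLines(sprintf("MODEL     %4d", r), con)
    writeLines(sprintf(
      "HETATM%5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(n), paste0(lig$atoms$element, seq_len(n)),
      p$xyz[, 1], p$xyz[, 2], p$xyz[, 3], lig$atoms$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  if (!is.null(csv_path)) {
    coms <- t(vapply(result$top_poses, pose_com, numeric(3)))
    utils::write.table(
      data.frame(rank = seq_along(result$top_poses),
                 lgfe = vapply(result$top_poses, function(p) p$lgfe,
                               numeric(1)),
                 cx = coms[, 1], cy = coms[, 2], cz = coms[, 3]),
      csv_path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(pdb_path)
}
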