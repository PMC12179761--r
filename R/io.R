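# Trajectory I/O: multi-model PDB (via bio3d), GROMACS GRO and extended XYZ
# (fixed-column parsers; no installed R package reads these two).
# GRO stores nm; everything is converted to Angstrom on read and back on write.
# GRO is written with 4 decimals in nm (the format permits variable precision),
# i.e. 1e-3 Angstrom round-trip resolution.

# crude element inference from an atom name ("OW1" -> "O", "CL" kept if known)
.two_letter <- c("CL", "BR", "NA", "MG", "ZN", "FE", "CA", "MN", "SE")
infer_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  ifelse(substr(nm, 1, 2) %in% .two_letter,
         paste0(substr(nm, 1, 1), tolower(substr(nm, 2, 2))),
         substr(nm, 1, 1))
}

# molecule ids from consecutive (resno, resname) runs, solute merged to one id
assign_roles <- function(resno, resname, solvent) {
  key <- paste(resno, resname)
  newmol <- c(TRUE, key[-1] != key[-length(key)])
  mol <- cumsum(newmol)
  role <- ifelse(resname %in% solvent, "solvent", "solute")
  # a molecule's role is that of its atoms; enforce consistency by majority
  solute_mols <- unique(mol[role == "solute"])
  if (length(solute_mols) > 0) {
    mol[role == "solute"] <- solute_mols[1]  # one solute molecule
  }
  list(molecule_id = mol, role = role)
}

#' Read a multi-frame trajectory with a solute/solvent partition
#'
#' Reads PDB (multi-model), GRO (concatenated frames) or extended XYZ
#' (concatenated frames plus a sidecar topology giving atoms-per-molecule).
#' Atoms whose residue/molecule name is in \code{solvent} are solvent; all
#' remaining atoms form the single solute molecule.
#'
#' @param path input file.
#' @param format one of \code{"pdb"}, \code{"gro"}, \code{"xyz"}; default
#'   guessed from the file extension.
#' @param solvent character vector of solvent residue/molecule names
#'   (e.g. \code{"SOL"}); names not matched are solute.
#' @param xyz_topology for XYZ only: path to a YAML sidecar or a list with a
#'   \code{molecules} entry, each molecule a list \code{(name, natoms, count)}
#'   in file order (bare XYZ carries no molecule grouping).
#' @return a \code{\link{trajectory}} (coordinates in Angstrom).
#' @export
read_trajectory <- function(path, format = NULL, solvent = character(),
                            xyz_topology = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("pdb", "gro", "xyz"))
  switch(format,
         pdb = read_traj_pdb(path, solvent),
         gro = read_traj_gro(path, solvent),
         xyz = read_traj_xyz(path, solvent, xyz_topology))
}

read_traj_pdb <- function(path, solvent) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- infer_element(at$elety)
  elem[is.na(elem) | elem == ""] <- infer_element(at$elety[is.na(elem) | elem == ""])
  ar <- assign_roles(at$resno, at$resid, solvent)
  topo <- data.frame(element = elem, name = at$elety, resname = at$resid,
                     resno = at$resno, molecule_id = ar$molecule_id,
                     role = ar$role, stringsAsFactors = FALSE)
  nf <- nrow(pdb$xyz)
  na <- nrow(at)
  coords <- array(NA_real_, c(na, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE)
  trajectory(topo, coords)
}

read_traj_gro <- function(path, solvent) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list(); topo <- NULL; boxes <- list()
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos])) && pos == length(lines)) break
    natoms <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(natoms))
      stop("format error: expected atom count at line ", pos + 1L)
    if (pos + 1L + natoms + 1L > length(lines))
      stop("format error: truncated frame starting at line ", pos)
    atom_lines <- lines[(pos + 2L):(pos + 1L + natoms)]
    resno <- as.integer(substr(atom_lines, 1, 5))
    resname <- trimws(substr(atom_lines, 6, 10))
    name <- trimws(substr(atom_lines, 11, 15))
    body <- substring(atom_lines, 21)
    xyz <- t(vapply(body, function(b) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(b), "\\s+")[[1]]))
      if (length(v) < 3 || anyNA(v[1:3]))
        stop("format error: bad coordinate fields in GRO atom line")
      v[1:3]
    }, numeric(3), USE.NAMES = FALSE))
    boxv <- suppressWarnings(as.numeric(
      strsplit(trimws(lines[pos + 2L + natoms]), "\\s+")[[1]]))[1:3]
    ft <- data.frame(resno = resno, resname = resname, name = name,
                     stringsAsFactors = FALSE)
    if (is.null(topo)) topo <- ft
    else if (nrow(ft) != nrow(topo))
      stop("frame-mismatch error: atom count differs across frames")
    frames[[length(frames) + 1L]] <- xyz * 10        # nm -> Angstrom
    boxes[[length(boxes) + 1L]] <- boxv * 10
    pos <- pos + 2L + natoms + 1L
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (!length(frames)) stop("format error: no frames in ", path)
  ar <- assign_roles(topo$resno, topo$resname, solvent)
  full <- data.frame(element = infer_element(topo$name), name = topo$name,
                     resname = topo$resname, resno = topo$resno,
                     molecule_id = ar$molecule_id, role = ar$role,
                     stringsAsFactors = FALSE)
  coords <- array(unlist(frames), c(nrow(full), 3L, length(frames)))
  box <- do.call(rbind, boxes)
  if (all(!is.finite(box)) || all(box == 0)) box <- NULL
  trajectory(full, coords, box)
}

read_traj_xyz <- function(path, solvent, xyz_topology) {
  if (is.null(xyz_topology))
    stop("XYZ input needs a sidecar topology (molecules with atom counts)")
  if (is.character(xyz_topology)) xyz_topology <- yaml::read_yaml(xyz_topology)
  mols <- xyz_topology$molecules
  if (is.null(mols)) stop("sidecar topology lacks a 'molecules' list")
  lines <- readLines(path)
  pos <- 1L; frames <- list(); elems <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(natoms)) stop("format error: expected atom count at line ", pos)
    if (pos + 1L + natoms > length(lines))
      stop("format error: truncated XYZ frame at line ", pos)
    al <- lines[(pos + 2L):(pos + 1L + natoms)]
    parts <- strsplit(trimws(al), "\\s+")
    el <- vapply(parts, `[`, "", 1L)
    xyz <- t(vapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p[2:4]))
      if (anyNA(v)) stop("format error: non-numeric XYZ coordinates")
      v
    }, numeric(3)))
    if (is.null(elems)) elems <- el
    else if (length(el) != length(elems))
      stop("frame-mismatch error: atom count differs across frames")
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + natoms
  }
  # expand sidecar molecule blocks into per-atom resname/resno
  resname <- character(0); resno <- integer(0); rn <- 0L
  for (m in mols) {
    cnt <- if (is.null(m$count)) 1L else as.integer(m$count)
    for (i in seq_len(cnt)) {
      rn <- rn + 1L
      resname <- c(resname, rep(m$name, m$natoms))
      resno <- c(resno, rep(rn, m$natoms))
    }
  }
  if (length(resname) != length(elems))
    stop("sidecar topology atom total (", length(resname),
         ") != XYZ atom count (", length(elems), ")")
  ar <- assign_roles(resno, resname, solvent)
  topo <- data.frame(element = elems, name = elems, resname = resname,
                     resno = resno, molecule_id = ar$molecule_id,
                     role = ar$role, stringsAsFactors = FALSE)
  coords <- array(unlist(frames), c(length(elems), 3L, length(frames)))
  trajectory(topo, coords)
}

#' Write a trajectory to PDB, GRO or XYZ
#'
#' The output is re-readable by \code{\link{read_trajectory}} with equal
#' topology and coordinates within the format's precision (PDB/GRO: 1e-3 A;
#' XYZ: 1e-6 A as written).
#'
#' @param traj a \code{\link{trajectory}}.
#' @param path output file.
#' @param format \code{"pdb"}, \code{"gro"} or \code{"xyz"}; default guessed
#'   from the extension.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path, format = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 1L) stop("empty frame list")
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("pdb", "gro", "xyz"))
  topo <- traj$topology
  nf <- n_frames(traj); na <- n_atoms(traj)
  switch(format,
    pdb = {
      xyz <- t(vapply(seq_len(nf),
                      function(f) as.vector(t(frame_coords(traj, f))),
                      numeric(3L * na)))
      if (nf == 1L) xyz <- matrix(xyz, nrow = 1L)
      bio3d::write.pdb(file = path, xyz = xyz, resno = topo$resno,
                       resid = topo$resname, eleno = seq_len(na),
                       elety = topo$name, elesy = topo$element)
    },
    gro = {
      con <- file(path, "w"); on.exit(close(con))
      for (f in seq_len(nf)) {
        xyz <- frame_coords(traj, f) / 10  # Angstrom -> nm
        writeLines(sprintf("frame %d", f), con)
        writeLines(sprintf("%5d", na), con)
        writeLines(sprintf("%5d%-5s%5s%5d%9.4f%9.4f%9.4f",
                           topo$resno %% 100000L, substr(topo$resname, 1, 5),
                           substr(topo$name, 1, 5), seq_len(na) %% 100000L,
                           xyz[, 1], xyz[, 2], xyz[, 3]), con)
        b <- if (is.null(traj$box)) c(0, 0, 0) else traj$box[f, ] / 10
        writeLines(sprintf("%10.5f%10.5f%10.5f", b[1], b[2], b[3]), con)
      }
    },
    xyz = {
      con <- file(path, "w"); on.exit(close(con))
      for (f in seq_len(nf)) {
        xyz <- frame_coords(traj, f)
        writeLines(sprintf("%d", na), con)
        writeLines(sprintf("frame %d", f), con)
        writeLines(sprintf("%-3s %14.6f %14.6f %14.6f",
                           topo$element, xyz[, 1], xyz[, 2], xyz[, 3]), con)
      }
    })
  invisible(path)
}
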