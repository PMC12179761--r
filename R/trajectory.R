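# Core trajectory container: a topology data.frame plus an [atoms x 3 x frames]
# coordinate array. Coordinates are Angstrom everywhere inside the package.

#' Construct a trajectory object
#'
#' A \code{trajectory} couples a topology (one row per atom) with an ordered
#' stack of coordinate frames. Coordinates are in Angstrom. The topology
#' partitions atoms into one solute molecule and zero or more solvent
#' molecules; all atoms of a molecule share a \code{molecule_id} and a role.
#'
#' @param topology data.frame with columns \code{element}, \code{name},
#'   \code{resname}, \code{resno}, \code{molecule_id}, \code{role}
#'   (\code{"solute"} or \code{"solvent"}).
#' @param coords numeric array \code{[n_atoms, 3, n_frames]} (a single
#'   \code{n_atoms x 3} matrix is promoted to one frame), Angstrom.
#' @param box optional \code{n_frames x 3} matrix of orthorhombic box lengths
#'   (Angstrom) used for minimum-image distances; \code{NULL} if aperiodic.
#' @return object of class \code{trajectory}.
#' @export
trajectory <- function(topology, coords, box = NULL) {
  stopifnot(is.data.frame(topology))
  req <- c("element", "name", "resname", "resno", "molecule_id", "role")
  miss <- setdiff(req, names(topology))
  if (length(miss)) stop("topology lacks columns: ", paste(miss, collapse = ", "))
  if (!all(topology$role %in% c("solute", "solvent")))
    stop("role must be 'solute' or 'solvent'")
  if (!any(topology$role == "solute"))
    stop("topology error: zero solute atoms (check the solvent selector)")
  # every molecule has a single role
  rle_chk <- tapply(topology$role, topology$molecule_id,
                    function(r) length(unique(r)))
  if (any(rle_chk != 1L)) stop("a molecule mixes solute and solvent atoms")
  if (length(unique(topology$molecule_id[topology$role == "solute"])) != 1L)
    stop("solute atoms must form exactly one molecule")
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3L, 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be an [atoms x 3 x frames] array")
  if (dim(coords)[1] != nrow(topology))
    stop("frame-mismatch error: coords rows != topology atoms")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!is.null(box)) {
    box <- matrix(box, ncol = 3L)
    if (nrow(box) == 1L) box <- box[rep(1L, dim(coords)[3]), , drop = FALSE]
    if (nrow(box) != dim(coords)[3]) stop("box rows != n_frames")
  }
  structure(list(topology = topology, coords = coords, box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<%s> %d atoms, %d frames, %d solvent molecules\n",
              class(x)[1], n_atoms(x), n_frames(x), n_solvent(x)))
  cat("  solute:", sum(x$topology$role == "solute"), "atoms;",
      if (is.null(x$box)) "aperiodic" else "periodic box", "\n")
  invisible(x)
}

#' Number of frames / atoms / solvent molecules in a trajectory
#' @param traj a \code{trajectory}
#' @return integer count
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_solvent <- function(traj)
  length(unique(traj$topology$molecule_id[traj$topology$role == "solvent"]))

#' Coordinates of one frame
#' @param traj a \code{trajectory}
#' @param i frame index (1-based)
#' @return \code{n_atoms x 3} matrix, Angstrom
#' @export
frame_coords <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  traj$coords[, , i, drop = TRUE]
}

# atom-index list per solvent molecule, in molecule_id order
solvent_molecules <- function(topology) {
  sel <- topology$role == "solvent"
  ids <- topology$molecule_id[sel]
  idx <- which(sel)
  split(idx, factor(ids, levels = unique(ids)))
}

solute_atoms <- function(topology) which(topology$role == "solute")

# geometric centers of groups of atom indices for one frame
group_centers <- function(xyz, groups) {
  t(vapply(groups, function(ix) colMeans(xyz[ix, , drop = FALSE]),
           numeric(3)))
}
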