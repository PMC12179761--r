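# Hand-off to constrained quantum-chemistry minimization: for a representative
# cluster frame, emit the frozen internal coordinates — (i) the declared solute
# torsions, (ii) each solvent molecule's center of mass in spherical
# coordinates about the solute center of mass (solute principal frame, physics
# convention: theta polar from +z, phi azimuthal from +x), (iii) three
# rigid-body orientation torsions per solvent molecule built from two solvent
# atoms and the two nearest solute anchor atoms, (iv) the solvent internal
# torsions from a solvent template (empty for water). Plus a reader for
# tabular stick spectra extracted from QM output.

.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, F = 18.998, Cl = 35.45, Na = 22.990,
                  K = 39.098, Mg = 24.305, Ca = 40.078, Zn = 65.38)

atom_masses <- function(element) {
  m <- .atomic_mass[element]
  m[is.na(m)] <- 12.011   # unknown elements treated as carbon-like
  unname(m)
}

# mass-weighted solute body frame: origin at solute COM, axes = gyration
# eigenvectors (right-handed, descending variance)
solute_body_frame <- function(xyz, topo) {
  si <- solute_atoms(topo)
  m <- atom_masses(topo$element[si])
  X <- xyz[si, , drop = FALSE]
  com <- colSums(X * m) / sum(m)
  Xc <- sweep(X, 2, com)
  gyr <- crossprod(Xc * m, Xc) / sum(m)
  ax <- eigen(gyr, symmetric = TRUE)$vectors
  if (det(ax) < 0) ax[, 3] <- -ax[, 3]
  list(com = com, axes = ax)
}

#' Frozen internal-coordinate specification for a cluster frame
#'
#' @param cluster a (reduced) cluster trajectory.
#' @param frame frame index of the representative conformation.
#' @param solute_torsions list of integer 4-vectors (atom indices into the
#'   cluster topology) declaring the solute torsion angles to freeze; may be
#'   empty for a rigid solute.
#' @param solvent_torsions list of integer 4-vectors of internal torsions
#'   within one solvent molecule, indices local to the molecule's atom order
#'   (e.g. \code{list()} for water, the two methyl torsions for DMSO).
#' @return object of class \code{constraint_spec}: \code{frozen_torsions}
#'   data.frame (\code{type} in \{solute, orientation, solvent_internal\},
#'   atom indices \code{i,j,k,l}), \code{frozen_spherical} data.frame
#'   (\code{molecule, r, theta, phi}; Angstrom / radians), and the body-frame
#'   definition used.
#' @export
build_constraints <- function(cluster, frame = 1L, solute_torsions = list(),
                              solvent_torsions = list()) {
  stopifnot(inherits(cluster, "trajectory"))
  topo <- cluster$topology
  xyz <- frame_coords(cluster, frame)
  bf <- solute_body_frame(xyz, topo)
  groups <- solvent_molecules(topo)
  si <- solute_atoms(topo)
  tors <- list()
  for (t in solute_torsions) {
    if (length(t) != 4L || any(t < 1L | t > nrow(topo)))
      stop("solute torsion must be 4 valid atom indices")
    tors[[length(tors) + 1L]] <- data.frame(type = "solute", i = t[1],
                                            j = t[2], k = t[3], l = t[4])
  }
  sph <- data.frame(molecule = integer(0), r = numeric(0),
                    theta = numeric(0), phi = numeric(0))
  for (g in seq_along(groups)) {
    ix <- groups[[g]]
    if (length(ix) < 2L)
      stop("solvent molecule ", g, " has < 2 atoms: cannot define ",
           "orientation torsions")
    m <- atom_masses(topo$element[ix])
    com <- colSums(xyz[ix, , drop = FALSE] * m) / sum(m)
    # spherical coordinates in the solute body frame
    v <- as.vector((com - bf$com) %*% bf$axes)
    r <- sqrt(sum(v^2))
    theta <- if (r > 0) acos(pmin(1, pmax(-1, v[3] / r))) else 0
    phi <- atan2(v[2], v[1])
    sph <- rbind(sph, data.frame(molecule = g, r = r, theta = theta,
                                 phi = phi))
    # two solute anchors nearest the solvent center (ties: lower index)
    cog <- colMeans(xyz[ix, , drop = FALSE])
    dd <- rowSums(sweep(xyz[si, , drop = FALSE], 2, cog)^2)
    anchors <- si[order(dd, si)][1:2]
    v1 <- ix[1]; v2 <- ix[2]
    ori <- rbind(c(anchors[2], anchors[1], v1, v2),
                 c(v1, anchors[1], anchors[2], v2),
                 c(anchors[1], v1, v2, anchors[2]))
    for (r_ in seq_len(3))
      tors[[length(tors) + 1L]] <- data.frame(type = "orientation",
                                              i = ori[r_, 1], j = ori[r_, 2],
                                              k = ori[r_, 3], l = ori[r_, 4])
    for (t in solvent_torsions) {
      gi <- ix[t]
      tors[[length(tors) + 1L]] <- data.frame(type = "solvent_internal",
                                              i = gi[1], j = gi[2],
                                              k = gi[3], l = gi[4])
    }
  }
  ft <- if (length(tors)) do.call(rbind, tors) else
    data.frame(type = character(0), i = integer(0), j = integer(0),
               k = integer(0), l = integer(0))
  if (anyDuplicated(ft[, c("i", "j", "k", "l")]))
    stop("duplicate torsion tuples in the constraint list")
  structure(list(frozen_torsions = ft, frozen_spherical = sph,
                 body_frame = bf, frame = frame),
            class = "constraint_spec")
}

#' Reconstruct Cartesian solvent centers of mass from a constraint spec
#'
#' Inverse of the spherical encoding (round-trip identity with
#' \code{\link{build_constraints}}).
#'
#' @param spec a \code{constraint_spec}.
#' @return matrix of solvent COM positions (lab frame), Angstrom.
#' @export
constraint_centers <- function(spec) {
  s <- spec$frozen_spherical
  local <- cbind(s$r * sin(s$theta) * cos(s$phi),
                 s$r * sin(s$theta) * sin(s$phi),
                 s$r * cos(s$theta))
  sweep(local %*% t(spec$body_frame$axes), 2, spec$body_frame$com, "+")
}

#' Write a constraint spec as commented plain text
#' @param spec a \code{constraint_spec}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_constraints <- function(spec, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# frozen internal coordinates for constrained minimization",
               "# spherical: physics convention, theta polar from +z of the",
               "# solute principal (body) frame, phi azimuthal from +x;",
               "# r in Angstrom, angles in radians",
               "# torsion <type> <i> <j> <k> <l>   (1-based atom indices)",
               "# spherical <molecule> <r> <theta> <phi>"), con)
  ft <- spec$frozen_torsions
  if (nrow(ft))
    writeLines(sprintf("torsion %s %d %d %d %d", ft$type, ft$i, ft$j,
                       ft$k, ft$l), con)
  s <- spec$frozen_spherical
  if (nrow(s))
    writeLines(sprintf("spherical %d %.9f %.9f %.9f", s$molecule, s$r,
                       s$theta, s$phi), con)
  invisible(path)
}

#' Parse a tabular stick spectrum
#'
#' Two-column (wavenumber, rotational strength) or labeled three-column
#' whitespace/comma-delimited text; \code{#} lines are comments.
#'
#' @param path input file.
#' @param dialect \code{"two_column"} (default) or \code{"labeled"} (third
#'   column = conformer label; must be constant per file).
#' @return a \code{\link{stick_spectrum}} (lines sorted by wavenumber).
#' @export
parse_sticks <- function(path, dialect = c("two_column", "labeled")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (!length(keep)) {
    warning("no stick lines in ", path)
    return(stick_spectrum(numeric(0), numeric(0),
                          label = tools::file_path_sans_ext(basename(path))))
  }
  nu <- numeric(0); R <- numeric(0); lab <- character(0)
  for (i in keep) {
    f <- strsplit(trimws(gsub(",", " ", lines[i])), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (length(f) < 2L || anyNA(v))
      stop("non-numeric stick entry at line ", i, " of ", path)
    if (v[1] < 0) stop("validation error: negative wavenumber at line ", i)
    nu <- c(nu, v[1]); R <- c(R, v[2])
    if (dialect == "labeled" && length(f) >= 3L) lab <- c(lab, f[3])
  }
  label <- if (dialect == "labeled" && length(lab)) lab[1] else
    tools::file_path_sans_ext(basename(path))
  stick_spectrum(nu, R, label)
}
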