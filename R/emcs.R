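# EMCS: per frame, the solvent molecules whose geometric centers fall inside
# an ellipsoid best fitting the solute are retained, giving a fixed-composition
# S(SOLV)M cluster subtrajectory. The ellipsoid axes are the eigenvectors of
# the solute gyration tensor; semi-axes are scaled gyration radii expanded to
# enclose every solute atom, plus a padding of about one solvation-shell width.

#' Ellipsoid best fitting a solute
#'
#' Center = solute geometric center; principal directions = eigenvectors of
#' the solute coordinate covariance (gyration tensor, population-normalized);
#' each semi-axis = \code{scale * sqrt(eigenvalue)}, expanded uniformly so
#' every solute atom lies inside, then increased by \code{padding}. A
#' degenerate (zero-variance) direction gets semi-axis \code{padding}.
#'
#' @param solute_coords \code{n x 3} matrix of solute coordinates, Angstrom.
#' @param padding shell padding added to every semi-axis, Angstrom
#'   (default 3.0, about one hydration-shell radius).
#' @param scale multiplier on the raw gyration semi-axes before the enclosing
#'   expansion (default 1: the bare ellipsoid just encloses the solute).
#' @return list of class \code{ellipsoid}: \code{center}, \code{axes}
#'   (3x3 orthonormal, columns = principal directions, descending), and
#'   \code{semi_axes} (a >= b >= c > 0, padded), \code{padding}.
#' @export
build_ellipsoid <- function(solute_coords, padding = 3.0, scale = 1.0) {
  if (!is.matrix(solute_coords)) solute_coords <- matrix(solute_coords, ncol = 3L)
  if (nrow(solute_coords) < 1L) stop("empty solute")
  if (padding < 0) stop("padding must be >= 0")
  if (scale <= 0) stop("scale must be > 0")
  center <- colMeans(solute_coords)
  Xc <- sweep(solute_coords, 2, center)
  gyr <- crossprod(Xc) / nrow(Xc)            # gyration tensor, 1/N
  eg <- eigen(gyr, symmetric = TRUE)         # eigenvalues descending
  axes <- eg$vectors
  if (det(axes) < 0) axes[, 3] <- -axes[, 3] # right-handed frame
  semi <- scale * sqrt(pmax(eg$values, 0))
  deg <- semi < 1e-8
  # expand non-degenerate axes so every solute atom is inside the bare
  # ellipsoid (degenerate directions carry no solute extent by construction)
  if (!all(deg)) {
    P <- Xc %*% axes
    s_eff <- ifelse(deg, 1, semi)
    m <- rowSums(sweep(P, 2, s_eff, "/")^2 * rep(!deg, each = nrow(P)))
    mmax <- max(m)
    if (mmax > 1) semi[!deg] <- semi[!deg] * sqrt(mmax)
  }
  semi <- semi + padding
  semi[deg] <- padding
  if (any(semi <= 0)) stop("degenerate ellipsoid: increase padding")
  structure(list(center = center, axes = axes, semi_axes = semi,
                 padding = padding), class = "ellipsoid")
}

#' Ellipsoid membership metric
#'
#' Returns \eqn{(x'/a)^2 + (y'/b)^2 + (z'/c)^2} with primed coordinates in
#' the ellipsoid principal frame and padded semi-axes; a point is inside iff
#' the metric is <= 1.
#'
#' @param points \code{m x 3} matrix (or length-3 vector) of positions.
#' @param e an \code{\link{build_ellipsoid}} result.
#' @return numeric vector of metrics (dimensionless).
#' @export
ellipsoid_metric <- function(points, e) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3L)
  P <- sweep(points, 2, e$center) %*% e$axes
  rowSums(sweep(P, 2, e$semi_axes, "/")^2)
}

# minimum-image shift of points towards a center under an orthorhombic box
min_image <- function(points, center, box) {
  if (is.null(box)) return(points)
  d <- sweep(points, 2, center)
  points - round(sweep(d, 2, box, "/")) %*% diag(box)
}

# per-frame solvent reference points (center of geometry, minimum image) and
# their ellipsoid metrics; shared by determine_M and emcs_extract.
# groups/sol_idx are precomputed once per trajectory by the callers.
frame_solvent_metrics <- function(traj, f, padding, scale, mode,
                                  sol_idx, groups, idx_flat = NULL,
                                  spa = NULL) {
  xyz <- frame_coords(traj, f)
  e <- build_ellipsoid(xyz[sol_idx, , drop = FALSE], padding, scale)
  box <- if (is.null(traj$box)) NULL else traj$box[f, ]
  if (mode == "cog") {
    if (!is.null(idx_flat)) {
      # homogeneous solvent: grouped column means via one reshape
      a <- xyz[idx_flat, , drop = FALSE]
      dim(a) <- c(spa, length(groups), 3L)
      pts <- matrix(colMeans(a), ncol = 3L)
    } else pts <- group_centers(xyz, groups)
    pts <- min_image(pts, e$center, box)
    metric <- ellipsoid_metric(pts, e)
  } else {  # nearest atom of each solvent molecule
    metric <- vapply(groups, function(ix) {
      p <- min_image(xyz[ix, , drop = FALSE], e$center, box)
      min(ellipsoid_metric(p, e))
    }, numeric(1))
  }
  list(metric = unname(metric), ellipsoid = e)
}

# flat index vector for homogeneous solvent (NULL if molecule sizes differ)
flat_solvent_index <- function(groups) {
  gsz <- lengths(groups)
  if (length(unique(gsz)) != 1L) return(NULL)
  unlist(groups, use.names = FALSE)
}

#' Fix the solvent count M of the EMCS cluster
#'
#' Counts, per frame, the solvent molecules whose reference point (center of
#' geometry by default) lies inside the solute-fitting ellipsoid, and fixes M
#' as the floor of a summary statistic of those counts (a fixed composition
#' across frames is required for the covariance analysis).
#'
#' @param traj a \code{\link{trajectory}}.
#' @param padding,scale passed to \code{\link{build_ellipsoid}} (recomputed
#'   per frame from that frame's solute).
#' @param statistic \code{"median"} (default), \code{"mode"} or \code{"min"}.
#' @param reference_point \code{"cog"} (default) or \code{"nearest_atom"}.
#' @return integer M (>= 1), with attribute \code{"counts"} (per frame).
#' @export
determine_M <- function(traj, padding = 3.0, scale = 1.0,
                        statistic = c("median", "mode", "min"),
                        reference_point = c("cog", "nearest_atom")) {
  statistic <- match.arg(statistic)
  reference_point <- match.arg(reference_point)
  mode <- if (reference_point == "cog") "cog" else "na"
  nf <- n_frames(traj)
  sol_idx <- solute_atoms(traj$topology)
  groups <- solvent_molecules(traj$topology)
  idx_flat <- flat_solvent_index(groups)
  spa <- if (is.null(idx_flat)) NULL else unname(lengths(groups)[1])
  counts <- vapply(seq_len(nf), function(f) {
    m <- frame_solvent_metrics(traj, f, padding, scale, mode,
                               sol_idx, groups, idx_flat, spa)$metric
    sum(m <= 1)
  }, integer(1))
  if (all(counts == 0))
    stop("empty-shell error: no solvent inside the ellipsoid in any frame; ",
         "increase padding")
  M <- switch(statistic,
              median = floor(stats::median(counts)),
              mode = as.integer(names(which.max(table(counts)))),
              min = min(counts))
  M <- max(1L, as.integer(M))
  attr(M, "counts") <- counts
  M
}

#' Extract the fixed-composition EMCS cluster subtrajectory
#'
#' Per frame, solvent molecules are ranked by ascending ellipsoid metric of
#' their reference point (ties broken by original molecule id); the first M
#' fill the cluster's solvent slots in that order. Requires homogeneous
#' solvent (equal atom count per solvent molecule) so that slots are
#' interchangeable coordinate blocks.
#'
#' @inheritParams determine_M
#' @param M number of solvent slots (1 <= M < number of solvent molecules).
#' @return a \code{cluster_trajectory}: a \code{\link{trajectory}} of the
#'   solute plus M renumbered solvent molecules, with fields \code{M},
#'   \code{slot_ids} (frames x M matrix of source molecule ids) and
#'   \code{provenance}.
#' @export
emcs_extract <- function(traj, M, padding = 3.0, scale = 1.0,
                         reference_point = c("cog", "nearest_atom")) {
  stopifnot(inherits(traj, "trajectory"))
  reference_point <- match.arg(reference_point)
  mode <- if (reference_point == "cog") "cog" else "na"
  topo <- traj$topology
  groups <- solvent_molecules(topo)
  if (M < 1L) stop("M must be >= 1")
  if (M >= length(groups))
    stop("M (", M, ") must be smaller than the solvent count (",
         length(groups), ")")
  gsz <- lengths(groups)
  if (length(unique(gsz)) != 1L)
    stop("solvent molecules differ in atom count; EMCS needs one solvent species")
  spa <- unname(gsz[1])                      # atoms per solvent molecule
  sol_idx <- solute_atoms(topo)
  ns <- length(sol_idx)
  nf <- n_frames(traj)
  na_out <- ns + M * spa
  coords <- array(NA_real_, c(na_out, 3L, nf))
  slot_ids <- matrix(NA_integer_, nf, M)
  mol_ids <- as.integer(names(groups))
  idx_flat <- flat_solvent_index(groups)
  grp_mat <- matrix(idx_flat, nrow = spa)     # spa x Nmol atom indices
  for (f in seq_len(nf)) {
    fm <- frame_solvent_metrics(traj, f, padding, scale, mode,
                                sol_idx, groups, idx_flat, spa)
    ord <- order(fm$metric, mol_ids)
    keep <- ord[seq_len(M)]
    xyz <- frame_coords(traj, f)
    box <- if (is.null(traj$box)) NULL else traj$box[f, ]
    sv <- xyz[as.vector(grp_mat[, keep]), , drop = FALSE]
    coords[, , f] <- rbind(xyz[sol_idx, , drop = FALSE],
                           min_image(sv, fm$ellipsoid$center, box))
    slot_ids[f, ] <- mol_ids[keep]
  }
  # cluster topology: solute block + M solvent slots renumbered 1..M
  tmpl <- topo[groups[[1]], , drop = FALSE]
  sv_res <- max(topo$resno[sol_idx]) + seq_len(M)
  sv_topo <- do.call(rbind, lapply(seq_len(M), function(s) {
    b <- tmpl
    b$resno <- sv_res[s]
    b$molecule_id <- max(topo$molecule_id[sol_idx]) + s
    b
  }))
  ct <- trajectory(rbind(topo[sol_idx, , drop = FALSE], sv_topo), coords)
  ct$M <- as.integer(M)
  ct$slot_ids <- slot_ids
  ct$provenance <- list(stage = "emcs", padding = padding, scale = scale,
                        reference_point = reference_point,
                        source_frames = nf)
  class(ct) <- c("cluster_trajectory", class(ct))
  ct
}

#' @export
print.cluster_trajectory <- function(x, ...) {
  NextMethod()
  cat(sprintf("  cluster: %d solvent slots (%s stage)\n",
              if (!is.null(x$k)) x$k else x$M,
              x$provenance$stage))
  invisible(x)
}
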