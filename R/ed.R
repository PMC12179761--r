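# Essential dynamics: the frames are roto-translationally fitted to a
# reference, the 3A x 3A covariance matrix of the analyzed Cartesian
# coordinates (population-normalized, 1/N) is diagonalized, and each frame is
# projected onto the orthonormal eigenvectors. The leading ("essential")
# eigenvectors are the collective internal coordinates along which the
# cluster fluctuates most.

#' Essential dynamics analysis of a (cluster) trajectory
#'
#' @param traj a \code{\link{trajectory}}, \code{cluster_trajectory} or
#'   \code{reduced_cluster_trajectory} with >= 2 frames.
#' @param fit_atoms atom indices for the superposition (default: solute
#'   atoms). The fit is applied to all atoms.
#' @param analyze_atoms atom indices entering the covariance (default: all
#'   atoms).
#' @param reference passed to \code{\link{fit_trajectory}} (default
#'   \code{"first"}).
#' @return object of class \code{ed_result}: \code{mean_coords} (3A vector,
#'   Angstrom), \code{eigenvalues} (descending, Angstrom^2, values below
#'   1e-12 clipped to 0), \code{eigenvectors} (3A x 3A, orthonormal columns,
#'   sign fixed so each column's largest-magnitude component is positive),
#'   \code{projections} (frames x 3A, Angstrom), \code{analyze_atoms},
#'   \code{fit_atoms}.
#' @export
ed_analyze <- function(traj, fit_atoms = NULL, analyze_atoms = NULL,
                       reference = "first") {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf < 2L) stop("rank error: essential dynamics needs >= 2 frames")
  if (is.null(fit_atoms)) fit_atoms <- solute_atoms(traj$topology)
  if (is.null(analyze_atoms)) analyze_atoms <- seq_len(n_atoms(traj))
  if (!length(analyze_atoms)) stop("analyze_atoms must be nonempty")
  fitted <- fit_trajectory(traj, fit_atoms, reference)
  # frames x 3A matrix of analyzed coordinates (x1,y1,z1,x2,...)
  A <- length(analyze_atoms)
  X <- t(matrix(aperm(fitted$coords[analyze_atoms, , , drop = FALSE],
                      c(2, 1, 3)), 3L * A, nf))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nf                    # population covariance
  eg <- eigen(C, symmetric = TRUE)
  ev <- eg$values
  ev[ev < 1e-12] <- 0
  V <- eg$vectors
  # deterministic sign: largest-magnitude component positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  proj <- Xc %*% V
  structure(list(mean_coords = mu, eigenvalues = ev, eigenvectors = V,
                 projections = proj, analyze_atoms = analyze_atoms,
                 fit_atoms = fit_atoms, n_frames = nf),
            class = "ed_result")
}

#' @export
print.ed_result <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  d60 <- essential_count(x, 0.6)
  cat(sprintf("<ed_result> %d frames, %d coordinates\n",
              x$n_frames, length(x$eigenvalues)))
  cat(sprintf("  total fluctuation %.4g A^2; %d eigenvector(s) cover 60%%\n",
              tot, d60))
  cat("  leading eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Number of essential eigenvectors for a variance fraction
#'
#' Smallest d whose cumulative eigenvalue fraction reaches
#' \code{variance_fraction} (boundary inclusive). The default 0.6 follows the
#' usual working rule that the essential subspace should carry at least 60
#' percent of the total internal fluctuation.
#'
#' @param ed an \code{\link{ed_analyze}} result.
#' @param variance_fraction target cumulative fraction in (0, 1].
#' @return integer d (0, with a warning, if total variance is zero).
#' @export
essential_count <- function(ed, variance_fraction = 0.6) {
  stopifnot(variance_fraction > 0, variance_fraction <= 1)
  tot <- sum(ed$eigenvalues)
  if (tot <= 0) {
    warning("zero total variance; no essential eigenvectors")
    return(0L)
  }
  cf <- cumsum(ed$eigenvalues) / tot
  which(cf >= variance_fraction - 1e-12)[1]
}

#' Project a structure onto essential eigenvectors
#'
#' The structure is roto-translationally fitted onto the ED mean structure
#' (over the fit atoms mapped into the analyzed set when possible, otherwise
#' all analyzed atoms) and the centered coordinates are dotted with the
#' requested eigenvectors.
#'
#' @param coords \code{A x 3} matrix over \code{ed$analyze_atoms} (already in
#'   analyzed-atom order).
#' @param ed an \code{\link{ed_analyze}} result.
#' @param vectors eigenvector indices (default first two).
#' @param fit logical: superpose onto the mean first (default TRUE).
#' @return numeric projection vector, Angstrom.
#' @export
project_structure <- function(coords, ed, vectors = 1:2, fit = TRUE) {
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 3L)
  A <- length(ed$analyze_atoms)
  if (nrow(coords) != A) stop("coords must cover the analyzed atom set")
  if (any(vectors < 1 | vectors > ncol(ed$eigenvectors)))
    stop("eigenvector index out of range")
  ref <- matrix(ed$mean_coords, ncol = 3L, byrow = TRUE)
  if (fit) coords <- fit_frame(coords, ref)$coords
  as.vector(crossprod(ed$eigenvectors[, vectors, drop = FALSE],
                      as.vector(t(coords)) - ed$mean_coords))
}
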