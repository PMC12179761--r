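# Roto-translational least-squares superposition (Kabsch, via SVD with a
# determinant correction so the rotation is always proper). The fit is
# computed on a subset of atoms and applied to all atoms, removing the
# external degrees of freedom before any covariance analysis.

#' Fit one frame onto a reference structure
#'
#' Weighted least-squares superposition: finds the proper rotation and
#' translation minimizing the (weighted) squared deviation of
#' \code{mobile[fit_atoms, ]} from \code{reference[fit_atoms, ]} and applies
#' the transformation to every atom of \code{mobile}.
#'
#' @param mobile \code{n x 3} coordinate matrix, Angstrom.
#' @param reference \code{n x 3} coordinate matrix of the reference.
#' @param fit_atoms integer indices of the atoms defining the fit
#'   (default: all); at least 3 non-collinear atoms.
#' @param weights optional non-negative per-fit-atom weights (default unit).
#' @return list with \code{coords} (all atoms transformed), \code{rotation}
#'   (3x3, det +1), \code{translation} (length 3) such that
#'   \code{fitted = mobile \%*\% t(R) + t}, and \code{rmsd} (Angstrom, over
#'   the fit atoms, weighted).
#' @export
fit_frame <- function(mobile, reference, fit_atoms = seq_len(nrow(mobile)),
                      weights = NULL) {
  if (!is.matrix(mobile)) mobile <- matrix(mobile, ncol = 3L)
  if (!is.matrix(reference)) reference <- matrix(reference, ncol = 3L)
  if (nrow(mobile) != nrow(reference))
    stop("mobile and reference atom counts differ")
  if (length(fit_atoms) < 3L) stop("fit-degeneracy error: need >= 3 fit atoms")
  X <- mobile[fit_atoms, , drop = FALSE]
  Y <- reference[fit_atoms, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, nrow(X)) else {
    if (length(weights) != nrow(X)) stop("weights length != fit subset size")
    weights
  }
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative, sum > 0")
  w <- w / sum(w)
  cx <- colSums(X * w); cy <- colSums(Y * w)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  # collinearity check on the fit subset
  sv_x <- svd(Xc * sqrt(w))$d
  if (sv_x[2] < 1e-9 * max(sv_x[1], 1e-12))
    stop("fit-degeneracy error: fit atoms are (nearly) collinear")
  H <- crossprod(Xc * w, Yc)                 # 3x3 weighted covariance
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cy - as.vector(R %*% cx)
  fitted_all <- sweep(mobile %*% t(R), 2, tr, "+")
  dev <- fitted_all[fit_atoms, , drop = FALSE] - Y
  rmsd <- sqrt(sum(w * rowSums(dev^2)))
  list(coords = fitted_all, rotation = R, translation = tr, rmsd = rmsd)
}

#' Fit every frame of a trajectory onto a reference
#'
#' @param traj a \code{\link{trajectory}} (or cluster trajectory).
#' @param fit_atoms atom indices used for the fit; default all solute atoms
#'   (in frozen-solute runs this places every frame in the solute body frame).
#' @param reference \code{"first"} (default), \code{"mean"} (iterated twice:
#'   fit to the first frame, fit to the resulting mean, refit to the new
#'   mean), or an explicit \code{n x 3} matrix.
#' @param weights optional per-fit-atom weights.
#' @return the trajectory with fitted coordinates plus attribute
#'   \code{"rmsd"} (per-frame fit RMSD).
#' @export
fit_trajectory <- function(traj, fit_atoms = NULL, reference = "first",
                           weights = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(fit_atoms)) fit_atoms <- solute_atoms(traj$topology)
  nf <- n_frames(traj)
  ref <- if (is.matrix(reference)) reference
         else frame_coords(traj, 1L)
  # validate the fit subset once (fit_frame checks size and collinearity),
  # then run a lean Kabsch loop over the remaining frames
  fit_pass <- function(ref) {
    out <- traj$coords
    rmsd <- numeric(nf)
    fr1 <- fit_frame(traj$coords[, , 1], ref, fit_atoms, weights)
    out[, , 1] <- fr1$coords
    rmsd[1] <- fr1$rmsd
    w <- if (is.null(weights)) rep(1, length(fit_atoms)) else weights
    w <- w / sum(w)
    Y <- ref[fit_atoms, , drop = FALSE]
    cy <- colSums(Y * w)
    Yc <- sweep(Y, 2, cy)
    for (f in seq_len(nf)[-1]) {
      xyz <- traj$coords[, , f]
      X <- xyz[fit_atoms, , drop = FALSE]
      cx <- colSums(X * w)
      Xc <- sweep(X, 2, cx)
      sv <- svd(crossprod(Xc * w, Yc))
      d <- sign(det(tcrossprod(sv$v, sv$u)))
      if (d == 0) d <- 1
      R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
      tr <- cy - as.vector(R %*% cx)
      fitted <- xyz %*% t(R)
      fitted[, 1] <- fitted[, 1] + tr[1]
      fitted[, 2] <- fitted[, 2] + tr[2]
      fitted[, 3] <- fitted[, 3] + tr[3]
      out[, , f] <- fitted
      dev <- fitted[fit_atoms, , drop = FALSE] - Y
      rmsd[f] <- sqrt(sum(w * rowSums(dev^2)))
    }
    list(coords = out, rmsd = rmsd)
  }
  p <- fit_pass(ref)
  if (identical(reference, "mean")) {
    for (it in 1:2) {
      ref <- apply(p$coords, c(1, 2), mean)
      p <- fit_pass(ref)
    }
  }
  traj$coords <- p$coords
  attr(traj, "rmsd") <- p$rmsd
  traj
}
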