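# Independent oracles used to cross-check the package's numerics. These
# deliberately take different algorithmic routes than the implementation:
# quaternion (Horn) superposition instead of SVD Kabsch, SVD-based PCA and
# explicit-loop covariance instead of eigen() on crossprod, scan-based greedy
# instead of a global sort, and plain per-line loops for spectra.

# Horn's quaternion method for the optimal proper rotation
quaternion_fit_rmsd <- function(mobile, reference) {
  n <- nrow(mobile)
  cx <- colMeans(mobile); cy <- colMeans(reference)
  X <- sweep(mobile, 2, cx); Y <- sweep(reference, 2, cy)
  S <- t(X) %*% Y
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  eg <- eigen(K, symmetric = TRUE)
  lmax <- eg$values[1]
  q <- eg$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  rmsd2 <- (sum(X^2) + sum(Y^2) - 2 * lmax) / n
  list(rotation = R, rmsd = sqrt(max(rmsd2, 0)))
}

# closed-form eigenvalues of a symmetric 3x3 matrix (trigonometric method)
eig3_closed_form <- function(A) {
  p1 <- A[1, 2]^2 + A[1, 3]^2 + A[2, 3]^2
  q <- sum(diag(A)) / 3
  p2 <- (A[1, 1] - q)^2 + (A[2, 2] - q)^2 + (A[3, 3] - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  if (p < 1e-14) return(rep(q, 3))
  B <- (A - q * diag(3)) / p
  r <- det(B) / 2
  r <- min(1, max(-1, r))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  sort(c(e1, 3 * q - e1 - e3, e3), decreasing = TRUE)
}

# explicit-loop population covariance of a frames x p matrix
loop_covariance <- function(X) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  C <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    C[i, j] <- sum((X[, i] - mu[i]) * (X[, j] - mu[j])) / n
  C
}

# PCA via SVD of the centered data matrix (independent of eigen())
svd_pca <- function(X) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  s <- svd(Xc)
  list(values = s$d^2 / n, vectors = s$v)
}

# scan-based greedy assignment: at each step pick the globally smallest
# remaining (center, solvent) distance (ties: lower center, then lower
# solvent index), independent of the package's sorted-pass implementation
scan_greedy <- function(D, n_retain) {
  nc <- nrow(D); ns <- ncol(D)
  filled <- integer(nc); taken <- logical(ns)
  pick <- replicate(nc, integer(0), simplify = FALSE)
  while (any(filled < n_retain)) {
    best <- c(Inf, NA, NA)
    for (ci in seq_len(nc)) {
      if (filled[ci] >= n_retain[ci]) next
      for (si in seq_len(ns)) {
        if (taken[si]) next
        if (D[ci, si] < best[1]) best <- c(D[ci, si], ci, si)
      }
    }
    if (!is.finite(best[1])) stop("oracle: infeasible")
    ci <- as.integer(best[2]); si <- as.integer(best[3])
    filled[ci] <- filled[ci] + 1L
    taken[si] <- TRUE
    pick[[ci]] <- c(pick[[ci]], si)
  }
  pick
}

# exhaustive conflict-free assignment minimizing total distance
exhaustive_min_assignment <- function(D, n_retain) {
  nc <- nrow(D); ns <- ncol(D)
  best <- NULL; best_cost <- Inf
  recurse <- function(ci, taken, sets, cost) {
    if (ci > nc) {
      if (cost < best_cost) {
        best_cost <<- cost
        best <<- sets
      }
      return()
    }
    avail <- which(!taken)
    if (length(avail) < n_retain[ci]) return()
    for (ch in if (n_retain[ci] > 0)
      asplit(utils::combn(avail, n_retain[ci]), 2) else list(integer(0))) {
      t2 <- taken; t2[ch] <- TRUE
      recurse(ci + 1L, t2, c(sets, list(as.integer(ch))),
              cost + sum(D[ci, ch]))
    }
  }
  recurse(1L, logical(ns), list(), 0)
  list(sets = best, cost = best_cost)
}

# small rigid water trajectory builder: one solute atom chain + waters at
# given per-frame molecule positions (list over frames of n_wat x 3 anchors)
toy_water_traj <- function(solute_xyz, water_pos_by_frame) {
  ns <- nrow(solute_xyz)
  wt <- data.frame(element = c("O", "H", "H"), name = c("OW", "HW1", "HW2"))
  wxyz <- matrix(c(0, 0.96, -0.24, 0, 0, 0.93, 0, 0, 0), 3, 3)
  n_wat <- nrow(water_pos_by_frame[[1]])
  topo <- rbind(
    data.frame(element = "C", name = paste0("C", seq_len(ns)),
               resname = "LIG", resno = 1L, molecule_id = 1L,
               role = "solute", stringsAsFactors = FALSE),
    do.call(rbind, lapply(seq_len(n_wat), function(i)
      data.frame(element = wt$element, name = wt$name, resname = "SOL",
                 resno = 1L + i, molecule_id = 1L + i, role = "solvent",
                 stringsAsFactors = FALSE))))
  nf <- length(water_pos_by_frame)
  coords <- array(NA_real_, c(ns + 3L * n_wat, 3L, nf))
  for (f in seq_len(nf)) {
    xyz <- solute_xyz
    for (i in seq_len(n_wat))
      xyz <- rbind(xyz, sweep(wxyz, 2, water_pos_by_frame[[f]][i, ], "+"))
    coords[, , f] <- xyz
  }
  trajectory(topo, coords)
}

# rigid 4-atom solute plus one single-atom "solvent" particle whose x
# position is fully controlled by the test (the solute anchors the fit)
one_particle_traj <- function(xs) {
  topo <- rbind(
    data.frame(element = "C", name = paste0("C", 1:4), resname = "LIG",
               resno = 1L, molecule_id = 1L, role = "solute",
               stringsAsFactors = FALSE),
    data.frame(element = "O", name = "OW", resname = "SOL", resno = 2L,
               molecule_id = 2L, role = "solvent", stringsAsFactors = FALSE))
  solute <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1),
                   4, 3, byrow = TRUE)
  nf <- length(xs)
  coords <- array(NA_real_, c(5, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- rbind(solute, c(3 + xs[f], 0, 0))
  trajectory(topo, coords)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
}
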