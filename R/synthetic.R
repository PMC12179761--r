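# Synthetic solvated-trajectory generator with known ground truth. It emulates
# the configurational structure the cluster pipeline is built for: a rigid
# solute carrying interaction sites, a tightly bound solvent population that
# hops among a catalog of site-bound arrangements with prescribed occupancies
# (the ground-truth basin weights), and a diffuse bulk population redrawn
# i.i.d. every frame. There are no dynamics: the selection, covariance and
# basin machinery under test is purely configurational.

# rigid L-alanine-like zwitterion, Angstrom; the two carboxylate oxygens (O,
# OXT) and the ammonium nitrogen (N) are the canonical aggregation sites
alanine_solute <- function() {
  data.frame(
    element = c("C", "H", "C", "H", "H", "H", "C", "O", "O",
                "N", "H", "H", "H"),
    name = c("CA", "HA", "CB", "HB1", "HB2", "HB3", "C", "O", "OXT",
             "N", "H1", "H2", "H3"),
    x = c(0.00, 0.30, -0.70, -1.40, -1.20, -0.10, 1.50, 2.20, 1.90,
          -1.00, -1.60, -1.55, -0.50),
    y = c(0.00, 0.00, -1.20, -1.10, -2.00, -1.55, 0.40, 1.00, -0.75,
          1.05, 1.00, 1.85, 1.30),
    z = c(0.00, 1.00, -0.35, 0.40, -1.00, 0.25, -0.30, 0.55, -1.10,
          0.45, -0.30, 0.95, 1.15),
    stringsAsFactors = FALSE)
}

# rigid SPC-like water template (local coordinates, Angstrom)
water_template <- function() {
  data.frame(element = c("O", "H", "H"), name = c("OW", "HW1", "HW2"),
             x = c(0, 0.9572, -0.2399), y = c(0, 0, 0.9266), z = c(0, 0, 0),
             stringsAsFactors = FALSE)
}

# anchor positions for one site-bound arrangement: waters stacked along a
# single outward direction at staggered radii. The stagger keeps the
# distance-ranked slot order stable against positional noise (the rank gap of
# ~0.6 A is 3-4 noise sigmas); the catalog states differ by the stack's
# direction (tilted off the site axis by the arrangement's angle), which
# separates the states by 1-2 A per water, far beyond the noise.
site_anchors <- function(site_center, axis, radii, tilt) {
  w <- axis / sqrt(sum(axis^2))
  # tilt out of the solute plane (+z for one site, -z for the other, via the
  # sign of tilt) so the two sites' stacks separate rather than compete
  ez <- c(0, 0, 1) - w[3] * w
  ez <- ez / sqrt(sum(ez^2))
  d <- cos(tilt) * w + sin(tilt) * ez
  t(vapply(radii, function(r) site_center + r * d, numeric(3)))
}

#' Specification of a synthetic solvated trajectory
#'
#' Defines the study conditions of a synthetic fixture: an L-alanine-like
#' rigid solute, a catalog of site-bound water arrangements with target
#' weights, a diffuse bulk population, per-molecule Gaussian positional noise
#' and a mandatory seed.
#'
#' @param arrangement_weights target occupancies of the bound-state catalog
#'   (must sum to 1); \code{numeric(0)} for a bulk-only fixture.
#' @param n_bound_carboxylate,n_bound_ammonium bound waters per site in every
#'   arrangement (defaults 4 and 3, the aqueous amino-acid convention of one
#'   water per carboxylate lone-pair region and one per ammonium hydrogen).
#' @param n_bulk diffuse bulk waters per frame.
#' @param sigma per-molecule rigid-translation noise, Angstrom (> 0).
#' @param n_frames frames to generate.
#' @param seed mandatory RNG seed.
#' @param bulk_shell c(r_in, r_out) of the bulk shell around the solute
#'   center, Angstrom.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(arrangement_weights = c(0.15, 0.25, 0.40, 0.20),
                           n_bound_carboxylate = 4L, n_bound_ammonium = 3L,
                           n_bulk = 20L, sigma = 0.15, n_frames = 1000L,
                           seed, bulk_shell = c(9, 13)) {
  if (missing(seed)) stop("a seed is mandatory (no unseeded generation)")
  if (sigma <= 0) stop("sigma must be > 0")
  if (length(arrangement_weights) &&
      abs(sum(arrangement_weights) - 1) > 1e-9)
    stop("arrangement weights must sum to 1")
  solute <- alanine_solute()
  sxyz <- as.matrix(solute[, c("x", "y", "z")])
  coo <- colMeans(sxyz[solute$name %in% c("O", "OXT"), ])
  nh3 <- sxyz[solute$name == "N", ]
  ctr <- colMeans(sxyz)
  n_arr <- length(arrangement_weights)
  radii_coo <- 2.3 + 0.8 * (seq_len(n_bound_carboxylate) - 1)
  radii_nh3 <- 2.3 + 0.8 * (seq_len(n_bound_ammonium) - 1)
  arrangements <- lapply(seq_len(n_arr), function(a) {
    tilt <- 0.35 * (a - 1)               # ~20 degrees between catalog states
    rbind(
      if (n_bound_carboxylate > 0)
        site_anchors(coo, coo - ctr, radii_coo, tilt),
      if (n_bound_ammonium > 0)
        site_anchors(nh3, nh3 - ctr, radii_nh3, -tilt))
  })
  for (a in arrangements) {
    if (!is.null(a) && nrow(a) > 1) {
      dd <- as.matrix(stats::dist(a))
      if (min(dd[upper.tri(dd)]) < 0.5)
        stop("spec error: site anchors closer than 0.5 Angstrom")
    }
  }
  structure(list(solute = solute, arrangements = arrangements,
                 weights = arrangement_weights,
                 n_bound = if (n_arr) nrow(arrangements[[1]]) else 0L,
                 n_bulk = as.integer(n_bulk), sigma = sigma,
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 bulk_shell = bulk_shell, center = ctr),
            class = "synthetic_spec")
}

#' Generate a synthetic solvated trajectory with ground-truth labels
#'
#' Per frame: an arrangement is drawn by its target weight; each bound water
#' is placed rigidly at its anchor plus an isotropic Gaussian displacement of
#' width \code{sigma}; bulk waters are scattered uniformly in the spherical
#' shell \code{bulk_shell} around the solute center, redrawn every frame. The
#' solute is rigid and identical in all frames.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return a \code{\link{trajectory}} (solvent residue name \code{SOL}) with
#'   attributes \code{"labels"} (true arrangement index per frame) and
#'   \code{"weights"} (the target occupancies).
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  solute <- spec$solute
  sxyz <- as.matrix(solute[, c("x", "y", "z")])
  wt <- water_template()
  wxyz <- as.matrix(wt[, c("x", "y", "z")])
  n_arr <- length(spec$weights)
  nb <- spec$n_bound; nk <- spec$n_bulk
  n_wat <- nb + nk
  na_tot <- nrow(solute) + 3L * n_wat
  nf <- spec$n_frames
  labels <- if (n_arr) sample.int(n_arr, nf, replace = TRUE,
                                  prob = spec$weights) else integer(nf)
  coords <- array(NA_real_, c(na_tot, 3L, nf))
  ns <- nrow(solute)
  r3 <- spec$bulk_shell^3
  coords[seq_len(ns), , ] <- sxyz[]            # rigid solute, every frame
  if (nb > 0) {
    # anchor coordinates per frame (nb x 3 x nf) + rigid per-molecule noise
    anch <- array(unlist(spec$arrangements), c(nb, 3L, n_arr))[, , labels,
                                                               drop = FALSE] +
      array(stats::rnorm(nb * 3L * nf, sd = spec$sigma), c(nb, 3L, nf))
    for (i in seq_len(nb)) {
      base <- ns + 3L * (i - 1L)
      for (j in 1:3) for (d in 1:3)
        coords[base + j, d, ] <- anch[i, d, ] + wxyz[j, d]
    }
  }
  if (nk > 0) {
    u <- stats::runif(nk * nf)
    r <- (r3[1] + u * (r3[2] - r3[1]))^(1 / 3)
    z <- stats::runif(nk * nf, -1, 1)
    phi <- stats::runif(nk * nf, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    pos <- array(rbind(r * s * cos(phi), r * s * sin(phi), r * z) +
                   spec$center, c(3L, nk, nf))
    for (i in seq_len(nk)) {
      base <- ns + 3L * nb + 3L * (i - 1L)
      for (j in 1:3) for (d in 1:3)
        coords[base + j, d, ] <- pos[d, i, ] + wxyz[j, d]
    }
  }
  topo <- rbind(
    data.frame(element = solute$element, name = solute$name, resname = "ALA",
               resno = 1L, molecule_id = 1L, role = "solute",
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(seq_len(n_wat), function(i)
      data.frame(element = wt$element, name = wt$name, resname = "SOL",
                 resno = 1L + i, molecule_id = 1L + i, role = "solvent",
                 stringsAsFactors = FALSE))))
  traj <- trajectory(topo, coords)
  attr(traj, "labels") <- labels
  attr(traj, "weights") <- spec$weights
  traj
}

#' Aggregation centers of the synthetic L-alanine-like solute
#'
#' Convenience accessor for the two canonical centers (carboxylate oxygen
#' pair and ammonium nitrogen) with the usual aqueous amino-acid retention
#' counts: four waters at the carboxylate, three at the ammonium.
#'
#' @param topology topology of a trajectory built on
#'   \code{\link{alanine_solute}} (atom names \code{O}, \code{OXT}, \code{N}).
#' @param n_carboxylate,n_ammonium per-center retention counts (4 and 3).
#' @return list of two \code{\link{aggregation_center}} objects.
#' @export
alanine_centers <- function(topology, n_carboxylate = 4L, n_ammonium = 3L) {
  oo <- which(topology$role == "solute" & topology$name %in% c("O", "OXT"))
  nn <- which(topology$role == "solute" & topology$name == "N")
  if (length(oo) != 2L || length(nn) != 1L)
    stop("topology does not look like the synthetic alanine solute")
  list(aggregation_center(oo, n_carboxylate, "COO"),
       aggregation_center(nn, n_ammonium, "NH3"))
}

#' Generate random per-conformer stick spectra with a known mixture
#'
#' Reproducible random line lists plus a designated weight vector, for
#' round-trip tests of broadening and weighted assembly.
#'
#' @param n_conformers number of conformers.
#' @param n_lines lines per conformer.
#' @param nu_range wavenumber range, cm^-1.
#' @param seed mandatory RNG seed.
#' @param weights mixture weights (default: normalized 1..n).
#' @return list with \code{sticks} (list of \code{\link{stick_spectrum}}) and
#'   \code{weights}.
#' @export
generate_sticks <- function(n_conformers, n_lines = 12,
                            nu_range = c(1200, 1500), seed,
                            weights = NULL) {
  if (missing(seed)) stop("a seed is mandatory (no unseeded generation)")
  set.seed(seed)
  if (is.null(weights)) weights <- seq_len(n_conformers) / sum(seq_len(n_conformers))
  if (length(weights) != n_conformers) stop("one weight per conformer")
  sticks <- lapply(seq_len(n_conformers), function(i)
    stick_spectrum(stats::runif(n_lines, nu_range[1], nu_range[2]),
                   stats::rnorm(n_lines), label = paste0("conf", i)))
  list(sticks = sticks, weights = weights)
}
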