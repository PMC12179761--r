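# VCD band-shape assembly: Gaussian broadening of signed stick spectra
# (rotational strengths), probability-weighted summation over cluster
# conformers, max-|I| = 100 normalization, and the normalized
# spectrum-agreement RMSD. The Gaussian bandwidth convention is the half-width
# at 1/e of peak height: I(nu0 +/- bw) = I(nu0)/e exactly.

#' Construct a stick spectrum
#'
#' @param wavenumber line positions, cm^-1 (> 0).
#' @param strength signed rotational strengths (arbitrary consistent units).
#' @param label conformer label.
#' @return object of class \code{stick_spectrum} (lines sorted by wavenumber).
#' @export
stick_spectrum <- function(wavenumber, strength, label = "") {
  if (length(wavenumber) != length(strength))
    stop("wavenumber and strength lengths differ")
  if (any(wavenumber <= 0)) stop("validation error: wavenumbers must be > 0")
  if (any(!is.finite(strength))) stop("non-finite rotational strength")
  o <- order(wavenumber)
  structure(list(lines = data.frame(wavenumber = wavenumber[o],
                                    strength = strength[o]),
                 label = label),
            class = "stick_spectrum")
}

#' @export
print.stick_spectrum <- function(x, ...) {
  cat(sprintf("<stick_spectrum> '%s': %d lines", x$label, nrow(x$lines)))
  if (nrow(x$lines))
    cat(sprintf(" in [%.1f, %.1f] cm^-1", min(x$lines$wavenumber),
                max(x$lines$wavenumber)))
  cat("\n")
  invisible(x)
}

new_spectrum <- function(grid, intensity, bandwidth = NA_real_,
                         normalized = FALSE) {
  structure(list(grid = grid, intensity = intensity, bandwidth = bandwidth,
                 normalized = normalized), class = "vcd_spectrum")
}

#' @export
print.vcd_spectrum <- function(x, ...) {
  cat(sprintf("<vcd_spectrum> %d points on [%.1f, %.1f] cm^-1%s%s\n",
              length(x$grid), min(x$grid), max(x$grid),
              if (is.finite(x$bandwidth))
                sprintf(", bandwidth %.1f", x$bandwidth) else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Gaussian broadening of a stick spectrum
#'
#' \eqn{I(\nu) = \sum_l R_l \exp(-((\nu - \nu_l)/\Delta)^2)} where
#' \eqn{\Delta} (\code{bandwidth}) is the half-width at 1/e of peak height.
#' The amplitude of each band is the rotational strength itself (no
#' frequency-dependent prefactor by default; comparisons downstream use
#' normalized intensities, where any constant prefactor cancels).
#'
#' @param stick a \code{\link{stick_spectrum}}.
#' @param bandwidth Gaussian 1/e half-width, cm^-1 (> 0; 7.0 is the usual
#'   mid-IR choice).
#' @param grid ascending uniform wavenumber grid, or \code{NULL} to span all
#'   lines +/- 4 bandwidths at \code{spacing}.
#' @param spacing grid spacing when \code{grid} is NULL (default 1 cm^-1).
#' @param nu_weighted logical: multiply each band by its wavenumber
#'   (off by default).
#' @return a \code{vcd_spectrum}.
#' @export
broaden <- function(stick, bandwidth = 7.0, grid = NULL, spacing = 1,
                    nu_weighted = FALSE) {
  stopifnot(inherits(stick, "stick_spectrum"))
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (!nrow(stick$lines)) {
    warning("empty line list: zero spectrum")
    if (is.null(grid)) grid <- seq(0, 1, length.out = 2L)
    return(new_spectrum(grid, rep(0, length(grid)), bandwidth))
  }
  if (is.null(grid)) {
    lo <- floor(min(stick$lines$wavenumber) - 4 * bandwidth)
    hi <- ceiling(max(stick$lines$wavenumber) + 4 * bandwidth)
    grid <- seq(lo, hi, by = spacing)
  }
  amp <- stick$lines$strength
  if (nu_weighted) amp <- amp * stick$lines$wavenumber
  # outer over (grid, lines)
  G <- exp(-((outer(grid, stick$lines$wavenumber, "-")) / bandwidth)^2)
  new_spectrum(grid, as.vector(G %*% amp), bandwidth)
}

#' Probability-weighted sum of conformer spectra
#'
#' \eqn{I_{tot} = \sum_j w_j I_j} on a common grid; the weights are the
#' conformer probabilities (renormalized to sum to 1 by default).
#'
#' @param spectra list of \code{vcd_spectrum} on identical grids.
#' @param weights non-negative weights, one per spectrum.
#' @param renormalize logical: scale weights to sum 1 (default TRUE).
#' @return a \code{vcd_spectrum}.
#' @export
assemble_spectra <- function(spectra, weights, renormalize = TRUE) {
  if (length(spectra) != length(weights)) stop("one weight per spectrum")
  if (any(weights < 0)) stop("weights must be >= 0")
  g <- spectra[[1]]$grid
  for (s in spectra)
    if (length(s$grid) != length(g) || any(abs(s$grid - g) > 1e-9))
      stop("grid mismatch: resample spectra to a common grid first")
  w <- weights
  if (renormalize && sum(w) > 0) w <- w / sum(w)
  I <- Reduce(`+`, Map(function(s, wi) wi * s$intensity, spectra, w))
  new_spectrum(g, I, spectra[[1]]$bandwidth)
}

#' Normalize a spectrum to max |I| = 100
#'
#' Scales so the largest absolute intensity is 100; sign structure is
#' preserved. Idempotent on already-normalized spectra.
#'
#' @param s a \code{vcd_spectrum}.
#' @return a normalized \code{vcd_spectrum}.
#' @export
normalize_spectrum <- function(s) {
  m <- max(abs(s$intensity))
  if (m == 0) stop("cannot normalize an all-zero spectrum")
  new_spectrum(s$grid, s$intensity * (100 / m), s$bandwidth, normalized = TRUE)
}

#' Normalized spectrum-agreement RMSD
#'
#' Both spectra are linearly resampled onto a common uniform grid over
#' \code{range}, each is normalized to max |I| = 100, and the value is
#' \eqn{\sqrt{\mathrm{mean}((I_a - I_b)^2)}}. Invariant to uniform positive
#' scaling of either input; zero iff the normalized resampled shapes are
#' identical. The comparison window is an explicit argument: restricting it
#' changes the value.
#'
#' @param a,b \code{vcd_spectrum} objects overlapping \code{range}.
#' @param range \code{c(nu_lo, nu_hi)} comparison window, cm^-1 (default the
#'   overlap of the two grids).
#' @param n_points resampling points (default 1 per cm^-1, min 50).
#' @return dimensionless RMSD on the 0-100 normalized intensity scale.
#' @export
spectrum_rmsd <- function(a, b, range = NULL, n_points = NULL) {
  if (is.null(range))
    range <- c(max(min(a$grid), min(b$grid)), min(max(a$grid), max(b$grid)))
  if (range[2] <= range[1]) stop("empty overlap between the spectra")
  if (min(a$grid) > range[1] + 1e-9 || max(a$grid) < range[2] - 1e-9 ||
      min(b$grid) > range[1] + 1e-9 || max(b$grid) < range[2] - 1e-9)
    stop("a spectrum does not cover the comparison range")
  if (is.null(n_points)) n_points <- max(50L, ceiling(diff(range)) + 1L)
  g <- seq(range[1], range[2], length.out = n_points)
  ia <- stats::approx(a$grid, a$intensity, g)$y
  ib <- stats::approx(b$grid, b$intensity, g)$y
  na_ <- max(abs(ia)); nb_ <- max(abs(ib))
  if (na_ == 0 || nb_ == 0) stop("all-zero spectrum in the comparison range")
  sqrt(mean((ia * 100 / na_ - ib * 100 / nb_)^2))
}

#' Write a spectrum as two-column text
#' @param s a \code{vcd_spectrum}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_spectrum <- function(s, path) {
  utils::write.table(data.frame(wavenumber = s$grid, intensity = s$intensity),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
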