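# Free-energy landscapes on essential-eigenvector projections, basin detection
# by steepest descent on the bin grid, statistical weights, and the
# three-sub-trajectory convergence check.

#' Free-energy landscape of essential-eigenvector projections
#'
#' Histograms the projections on 1 or 2 eigenvectors and Boltzmann-inverts:
#' \eqn{\Delta G(bin) = -\ln(count/count_{max})} in kT units, so the most
#' populated bin sits at exactly 0. Empty bins carry a finite cap (max
#' occupied \eqn{\Delta G} + 1) rather than infinities.
#'
#' @param projections an \code{\link{ed_analyze}} result or a frames x d
#'   numeric matrix of projections (Angstrom).
#' @param dims eigenvector indices defining the landscape (length 1 or 2,
#'   default \code{1:2}).
#' @param n_bins bins per dimension (>= 4, default 64).
#' @param temperature_K temperature declared for the kT unit (default 300;
#'   the surface itself is in kT, the declaration travels with the object).
#' @return object of class \code{free_energy_landscape}: \code{edges},
#'   \code{mids}, \code{counts}, \code{deltaG} (kT), \code{cap},
#'   \code{frame_bin} (linear bin index per frame), \code{proj} (frames x d).
#' @export
build_landscape <- function(projections, dims = 1:2, n_bins = 64,
                            temperature_K = 300) {
  if (inherits(projections, "ed_result"))
    projections <- projections$projections
  if (!is.matrix(projections)) projections <- matrix(projections, ncol = 1L)
  d <- length(dims)
  if (d < 1L || d > 2L) stop("landscape supports 1 or 2 dimensions")
  if (n_bins < 4L) stop("n_bins must be >= 4")
  n_bins <- as.integer(n_bins)
  if (max(dims) > ncol(projections)) stop("dims exceed projection columns")
  P <- projections[, dims, drop = FALSE]
  nf <- nrow(P)
  edges <- vector("list", d); bin <- matrix(NA_integer_, nf, d)
  degenerate <- FALSE
  for (j in seq_len(d)) {
    rng <- range(P[, j])
    span <- diff(rng)
    if (span <= 0) {
      warning("all projections identical in dimension ", j,
              "; degenerate single-bin landscape")
      degenerate <- TRUE
      span <- 1
    }
    lo <- rng[1] - 0.025 * span; hi <- rng[2] + 0.025 * span
    edges[[j]] <- seq(lo, hi, length.out = n_bins + 1L)
    b <- findInterval(P[, j], edges[[j]], rightmost.closed = TRUE)
    bin[, j] <- pmin.int(pmax.int(b, 1L), n_bins)
  }
  lin <- bin[, 1]
  if (d == 2L) lin <- bin[, 1] + (bin[, 2] - 1L) * n_bins
  dims_out <- rep(n_bins, d)
  counts <- array(tabulate(lin, nbins = prod(dims_out)), dims_out)
  dg <- -log(counts / max(counts))
  occ <- counts > 0
  cap <- max(dg[occ]) + 1
  dg[!occ] <- cap
  structure(list(dims = dims, edges = edges,
                 mids = lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2),
                 counts = counts, deltaG = dg, cap = cap,
                 temperature_K = temperature_K, n_bins = n_bins,
                 frame_bin = lin, proj = P, degenerate = degenerate),
            class = "free_energy_landscape")
}

#' @export
print.free_energy_landscape <- function(x, ...) {
  cat(sprintf("<free_energy_landscape> %dD, %d bins/dim, %d frames, cap %.2f kT\n",
              length(x$edges), x$n_bins, length(x$frame_bin), x$cap))
  invisible(x)
}

#' Export a landscape as gridded text
#'
#' Writes (x, deltaG) or (x, y, deltaG) rows for plotting.
#' @param fel a \code{\link{build_landscape}} result.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_landscape <- function(fel, path) {
  d <- length(fel$edges)
  if (d == 1L) {
    df <- data.frame(x = fel$mids[[1]], deltaG = as.vector(fel$deltaG))
  } else {
    g <- expand.grid(x = fel$mids[[1]], y = fel$mids[[2]])
    df <- cbind(g, deltaG = as.vector(fel$deltaG))
  }
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# neighbor linear indices of a bin on the grid (8-neighborhood in 2D)
grid_neighbors <- function(lin, nb, d) {
  if (d == 1L) {
    nbr <- c(lin - 1L, lin + 1L)
    return(nbr[nbr >= 1L & nbr <= nb])
  }
  i <- (lin - 1L) %% nb + 1L
  j <- (lin - 1L) %/% nb + 1L
  ii <- pmax(i - 1L, 1L):pmin(i + 1L, nb)
  jj <- pmax(j - 1L, 1L):pmin(j + 1L, nb)
  g <- as.matrix(expand.grid(ii, jj))
  out <- g[, 1] + (g[, 2] - 1L) * nb
  out[out != lin]
}

#' Detect free-energy basins and their statistical weights
#'
#' Each occupied bin with \eqn{\Delta G \le} \code{g_cut} descends to its
#' lowest neighbor (plateaus broken toward the lower linear bin index) until a
#' local minimum is reached; bins sharing a minimum form a basin. Basins whose
#' depth below the lowest connecting saddle is less than \code{min_depth} are
#' merged into the deeper neighbor. Basin probability = member frame count /
#' total frames (frames in bins above \code{g_cut} stay unassigned, so the
#' probabilities sum to the retained-frame fraction; \code{renormalize} scales
#' them to sum to 1 for spectrum weighting). The representative frame is the
#' frame whose projection is nearest to the mode-bin center.
#'
#' @param fel a \code{\link{build_landscape}} result.
#' @param g_cut occupancy cutoff in kT (default 4).
#' @param min_depth minimum basin depth below its lowest saddle, kT
#'   (default 1).
#' @param renormalize logical: scale probabilities to sum to 1 (default FALSE).
#' @return object of class \code{basin_set}: \code{basins} data.frame
#'   (\code{label, probability, n_frames, representative_frame, mode_bin}),
#'   \code{frame_basin} (basin id per frame, NA above \code{g_cut}),
#'   \code{retained_fraction}.
#' @export
detect_basins <- function(fel, g_cut = 4, min_depth = 1, renormalize = FALSE) {
  stopifnot(inherits(fel, "free_energy_landscape"))
  d <- length(fel$edges); nb <- fel$n_bins
  dg <- as.vector(fel$deltaG)
  counts <- as.vector(fel$counts)
  domain <- which(counts > 0 & dg <= g_cut)
  if (!length(domain)) {
    warning("no occupied bin below g_cut; empty basin set")
    return(structure(list(basins = data.frame(label = character(0),
                                              probability = numeric(0),
                                              n_frames = integer(0),
                                              representative_frame = integer(0),
                                              mode_bin = integer(0)),
                          frame_basin = rep(NA_integer_,
                                            length(fel$frame_bin)),
                          retained_fraction = 0, g_cut = g_cut),
                     class = "basin_set"))
  }
  in_dom <- logical(length(dg)); in_dom[domain] <- TRUE
  # steepest descent with memoization
  sink_of <- integer(length(dg))             # 0 = unresolved
  descend <- function(b) {
    path <- integer(0)
    while (sink_of[b] == 0L) {
      path <- c(path, b)
      nbr <- grid_neighbors(b, nb, d)
      nbr <- nbr[in_dom[nbr]]
      if (!length(nbr)) break
      cand <- c(b, nbr)
      best <- cand[order(dg[cand], cand)][1]  # plateau -> lower linear index
      if (best == b) break
      b <- best
      if (b %in% path) break                  # safety on flat cycles
    }
    s <- if (sink_of[b] != 0L) sink_of[b] else b
    sink_of[path] <<- s
    sink_of[b] <<- s
    s
  }
  for (b in domain) descend(b)
  sinks <- sort(unique(sink_of[domain]))
  basin_id <- match(sink_of, sinks)          # per bin (domain only meaningful)
  # merge shallow basins across their lowest saddles until stable
  repeat {
    nbas <- length(sinks)
    if (nbas <= 1L) break
    saddle <- matrix(Inf, nbas, nbas)
    for (b in domain) {
      ib <- basin_id[b]
      for (nbr in grid_neighbors(b, nb, d)) {
        if (!in_dom[nbr]) next
        jb <- basin_id[nbr]
        if (jb != ib) {
          h <- max(dg[b], dg[nbr])
          if (h < saddle[ib, jb]) saddle[ib, jb] <- saddle[jb, ib] <- h
        }
      }
    }
    minima <- dg[sinks]
    depth <- vapply(seq_len(nbas),
                    function(i) min(saddle[i, -i]) - minima[i], numeric(1))
    shallow <- which(is.finite(depth) & depth < min_depth)
    if (!length(shallow)) break
    # absorb the shallowest under-depth basin into its neighbor across the
    # lowest connecting saddle (one merge per pass, then re-evaluate)
    i <- shallow[which.max(minima[shallow])]
    j <- which.min(saddle[i, ] + ifelse(seq_len(nbas) == i, Inf, 0))
    sink_of[sink_of == sinks[i]] <- sinks[j]
    sinks <- sort(unique(sink_of[domain]))
    basin_id <- match(sink_of, sinks)
  }
  nbas <- length(sinks)
  # frame assignment
  fb_bin <- fel$frame_bin
  frame_basin <- ifelse(in_dom[fb_bin], basin_id[fb_bin], NA_integer_)
  nf <- length(fb_bin)
  n_mem <- tabulate(frame_basin, nbins = nbas)
  prob <- n_mem / nf
  retained <- sum(n_mem) / nf
  if (renormalize && sum(prob) > 0) prob <- prob / sum(prob)
  # mode bin and representative frame per basin
  mode_bin <- integer(nbas); rep_frame <- integer(nbas)
  for (i in seq_len(nbas)) {
    members <- domain[basin_id[domain] == i]
    mode_bin[i] <- members[which.min(dg[members])]
    ctr <- bin_center(mode_bin[i], fel)
    cand <- which(!is.na(frame_basin) & frame_basin == i)
    dif <- sweep(fel$proj[cand, , drop = FALSE], 2, ctr)
    rep_frame[i] <- cand[which.min(rowSums(dif^2))]
  }
  ord <- order(-prob)
  basins <- data.frame(label = paste0("B", seq_len(nbas)),
                       probability = prob[ord], n_frames = n_mem[ord],
                       representative_frame = rep_frame[ord],
                       mode_bin = mode_bin[ord],
                       stringsAsFactors = FALSE)
  structure(list(basins = basins,
                 frame_basin = match(frame_basin, ord),
                 retained_fraction = retained, g_cut = g_cut,
                 min_depth = min_depth, renormalized = renormalize,
                 mode_centers = t(vapply(basins$mode_bin,
                                         bin_center, numeric(length(fel$edges)),
                                         fel = fel))),
            class = "basin_set")
}

bin_center <- function(lin, fel) {
  nb <- fel$n_bins
  if (length(fel$edges) == 1L) return(fel$mids[[1]][lin])
  i <- (lin - 1L) %% nb + 1L
  j <- (lin - 1L) %/% nb + 1L
  c(fel$mids[[1]][i], fel$mids[[2]][j])
}

#' @export
print.basin_set <- function(x, ...) {
  cat(sprintf("<basin_set> %d basin(s), retained fraction %.3f%s\n",
              nrow(x$basins), x$retained_fraction,
              if (isTRUE(x$renormalized)) " (renormalized)" else ""))
  print(x$basins, row.names = FALSE)
  invisible(x)
}

#' Combine solute and cluster basin weights
#'
#' The statistical weight of a solute-conformer/cluster-basin pair is the
#' product \eqn{w_{ji} = p_i \, p_{ji}} of the solute basin weight and the
#' cluster basin weight obtained under that (frozen) solute conformation.
#'
#' @param solute_weights numeric vector of solute conformer weights
#'   \eqn{p_i} (each in [0, 1]), optionally named.
#' @param cluster_basins a single \code{\link{detect_basins}} result or a
#'   list with one basin set per solute conformer.
#' @return data.frame with \code{solute_state}, \code{basin},
#'   \code{representative_frame} and \code{weight}.
#' @export
combine_weights <- function(solute_weights, cluster_basins) {
  if (inherits(cluster_basins, "basin_set"))
    cluster_basins <- rep(list(cluster_basins), length(solute_weights))
  if (length(cluster_basins) != length(solute_weights))
    stop("one basin set per solute weight required")
  if (any(solute_weights < 0 | solute_weights > 1))
    stop("solute weights must lie in [0, 1]")
  nm <- names(solute_weights)
  if (is.null(nm)) nm <- paste0("S", seq_along(solute_weights))
  out <- do.call(rbind, lapply(seq_along(solute_weights), function(i) {
    b <- cluster_basins[[i]]$basins
    data.frame(solute_state = nm[i], basin = b$label,
               representative_frame = b$representative_frame,
               weight = solute_weights[i] * b$probability,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Sub-trajectory convergence check of the basin weights
#'
#' Splits the cluster trajectory into \code{n_splits} contiguous blocks,
#' reruns the full ED + landscape + basin pipeline on each block, matches
#' basins across blocks by mode-bin-center proximity in projection space, and
#' reports the per-basin probability spread. Converged sampling should give a
#' small maximum deviation (the working criterion used here is < 0.05).
#'
#' @param cluster a (reduced) cluster trajectory.
#' @param n_splits number of contiguous blocks (default 3).
#' @param dims,n_bins,temperature_K passed to \code{\link{build_landscape}}.
#' @param g_cut,min_depth,renormalize passed to \code{\link{detect_basins}}.
#' @param fit_atoms,analyze_atoms passed to \code{\link{ed_analyze}}.
#' @return list: \code{splits} (per-block basin sets), \code{matched}
#'   (basin-probability matrix, blocks x basins, NA where unmatched),
#'   \code{max_deviation}, \code{count_mismatch} (TRUE if blocks disagree on
#'   the number of basins).
#' @export
convergence_check <- function(cluster, n_splits = 3, dims = 1:2, n_bins = 64,
                              temperature_K = 300, g_cut = 4, min_depth = 1,
                              renormalize = TRUE,
                              fit_atoms = NULL, analyze_atoms = NULL) {
  nf <- n_frames(cluster)
  if (nf < 2L * n_splits)
    stop("too few frames (", nf, ") for ", n_splits, " splits")
  bounds <- floor(seq(0, nf, length.out = n_splits + 1L))
  splits <- lapply(seq_len(n_splits), function(s) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    sub <- cluster
    sub$coords <- cluster$coords[, , idx, drop = FALSE]
    if (!is.null(sub$slot_ids))
      sub$slot_ids <- sub$slot_ids[idx, , drop = FALSE]
    if (!is.null(sub$assignment))
      sub$assignment <- sub$assignment[idx, , drop = FALSE]
    ed <- ed_analyze(sub, fit_atoms, analyze_atoms)
    fel <- build_landscape(ed, dims, n_bins, temperature_K)
    detect_basins(fel, g_cut, min_depth, renormalize)
  })
  nb <- vapply(splits, function(s) nrow(s$basins), integer(1))
  count_mismatch <- length(unique(nb)) > 1L
  k <- nb[1]
  matched <- matrix(NA_real_, n_splits, k)
  matched[1, ] <- splits[[1]]$basins$probability
  ref_ctr <- splits[[1]]$mode_centers
  for (s in 2:n_splits) {
    ctr <- splits[[s]]$mode_centers
    used <- logical(k)
    for (b in seq_len(nrow(ctr))) {
      dd <- rowSums(sweep(ref_ctr, 2, ctr[b, ])^2)
      dd[used] <- Inf
      j <- which.min(dd)
      if (is.finite(dd[j])) {
        matched[s, j] <- splits[[s]]$basins$probability[b]
        used[j] <- TRUE
      }
    }
  }
  dev <- apply(matched, 2, function(p)
    if (all(is.na(p))) NA_real_ else diff(range(p, na.rm = TRUE)))
  list(splits = splits, matched = matched,
       max_deviation = suppressWarnings(max(dev, na.rm = TRUE)),
       count_mismatch = count_mismatch)
}
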