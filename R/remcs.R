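# rEMCS: per frame, reduce the EMCS cluster to the solvent molecules bound at
# preselected solute aggregation centers (chemical groups expected to undergo
# tighter solute-solvent interactions, e.g. a carboxylate or an ammonium
# group). With l centers retaining n_i molecules each, the reduced cluster
# holds k = sum(n_i) solvent molecules per frame; for uniform n this is the
# k = n x l composition. Conflicts (one molecule closest to two centers) are
# resolved by a deterministic global greedy pass over all (center, solvent)
# distances in ascending order.

#' Define a solute aggregation center
#'
#' @param atoms integer indices (into the cluster topology) of the solute
#'   atoms forming the chemical group, e.g. the two carboxylate oxygens.
#' @param n_retain number of solvent molecules this center keeps per frame.
#' @param label short name used in slot assignments and reports.
#' @return object of class \code{aggregation_center}.
#' @export
aggregation_center <- function(atoms, n_retain, label) {
  atoms <- as.integer(atoms)
  if (!length(atoms)) stop("center '", label, "': empty atom set")
  if (n_retain < 0) stop("n_retain must be >= 0")
  structure(list(atoms = atoms, n_retain = as.integer(n_retain),
                 label = as.character(label)), class = "aggregation_center")
}

# distances between every center and every solvent slot, one frame
center_solvent_distances <- function(xyz, centers, slots, distance_mode) {
  nc <- length(centers); ns <- length(slots)
  if (distance_mode == "nearest_atom") {
    # one (all center atoms) x (all solvent atoms) squared-distance matrix,
    # then a grouped min over (center, molecule) blocks
    ca_idx <- unlist(lapply(centers, `[[`, "atoms"), use.names = FALSE)
    sa_idx <- unlist(slots, use.names = FALSE)
    ca <- xyz[ca_idx, , drop = FALSE]
    sa <- xyz[sa_idx, , drop = FALSE]
    d2 <- outer(rowSums(ca^2), rowSums(sa^2), "+") - 2 * tcrossprod(ca, sa)
    gsz <- lengths(slots)
    if (length(unique(gsz)) == 1L) {
      spa <- gsz[1]
      a <- array(d2, c(nrow(d2), spa, ns))
      am <- a[, 1, , drop = TRUE]
      if (spa > 1) for (j in 2:spa) am <- pmin(am, a[, j, , drop = TRUE])
      am <- matrix(am, nrow(d2), ns)         # atom-by-molecule minima
    } else {
      scol <- rep(seq_len(ns), gsz)
      am <- t(vapply(seq_len(nrow(d2)), function(i)
        as.numeric(tapply(d2[i, ], scol, min)), numeric(ns)))
    }
    crow <- rep(seq_len(nc), vapply(centers, function(c) length(c$atoms),
                                    integer(1)))
    D <- matrix(Inf, nc, ns)
    for (i in seq_len(nrow(am)))
      D[crow[i], ] <- pmin(D[crow[i], ], am[i, ])
    sqrt(pmax(D, 0))
  } else {
    cc <- t(vapply(centers, function(c)
      colMeans(xyz[c$atoms, , drop = FALSE]), numeric(3)))
    sc <- t(vapply(slots, function(ix)
      colMeans(xyz[ix, , drop = FALSE]), numeric(3)))
    d2 <- outer(rowSums(cc^2), rowSums(sc^2), "+") - 2 * tcrossprod(cc, sc)
    sqrt(pmax(d2, 0))
  }
}

# deterministic global greedy assignment: walk (center, solvent) pairs in
# ascending distance (ties: center order, then slot order), assign a solvent
# to at most one center until every center is full
greedy_assign <- function(D, n_retain) {
  nc <- nrow(D); ns <- ncol(D)
  ord <- order(as.vector(D), rep(seq_len(nc), ns),
               rep(seq_len(ns), each = nc))
  filled <- integer(nc)
  taken <- logical(ns)
  pick <- vector("list", nc)
  for (o in ord) {
    ci <- (o - 1L) %% nc + 1L
    si <- (o - 1L) %/% nc + 1L
    if (taken[si] || filled[ci] >= n_retain[ci]) next
    filled[ci] <- filled[ci] + 1L
    taken[si] <- TRUE
    pick[[ci]] <- c(pick[[ci]], si)
    if (all(filled == n_retain)) break
  }
  if (!all(filled == n_retain)) {
    short <- which(filled < n_retain)[1]
    stop("center ", short, " cannot fill its ", n_retain[short],
         " slots (only ", filled[short], " candidates)")
  }
  pick  # per center, slot indices in ascending-distance rank order
}

#' Reduce an EMCS cluster to site-bound solvent molecules (rEMCS)
#'
#' Per frame, every (center, solvent) distance is computed (minimum atom-atom
#' distance by default), all pairs are sorted globally by ascending distance,
#' and solvent molecules are assigned greedily to at most one center until
#' each center holds its \code{n_retain} molecules. Output slots are ordered
#' by (center order as given, within-center distance rank), so the reduced
#' cluster is a fixed-composition trajectory of the solute plus k solvent
#' molecules.
#'
#' @param cluster a \code{cluster_trajectory} from \code{\link{emcs_extract}}
#'   (or any homogeneous-solvent \code{\link{trajectory}}; running rEMCS
#'   directly is supported for small systems, EMCS-first is canonical).
#' @param centers list of \code{\link{aggregation_center}} objects (solute
#'   atom indices refer to \code{cluster$topology}).
#' @param distance_mode \code{"nearest_atom"} (default) or \code{"com"}
#'   (centroid-to-centroid).
#' @return a \code{reduced_cluster_trajectory} with fields \code{k},
#'   \code{slot_ids}, and \code{assignment} (frames x k matrix of center
#'   labels).
#' @export
remcs_reduce <- function(cluster, centers,
                         distance_mode = c("nearest_atom", "com")) {
  stopifnot(inherits(cluster, "trajectory"))
  distance_mode <- match.arg(distance_mode)
  if (!length(centers)) stop("centers must be nonempty")
  if (inherits(centers, "aggregation_center")) centers <- list(centers)
  topo <- cluster$topology
  for (ce in centers) {
    if (!all(topo$role[ce$atoms] == "solute"))
      stop("center '", ce$label, "' selects non-solute atoms")
  }
  groups <- solvent_molecules(topo)
  M <- length(groups)
  n_retain <- vapply(centers, `[[`, integer(1), "n_retain")
  k <- sum(n_retain)
  if (k > M)
    stop("infeasible-reduction error: sum(n_retain) = ", k,
         " exceeds the cluster's ", M, " solvent molecules")
  gsz <- lengths(groups)
  if (k > 0 && length(unique(gsz)) != 1L)
    stop("solvent molecules differ in atom count")
  spa <- if (k > 0) unname(gsz[1]) else 0L
  sol_idx <- solute_atoms(topo)
  ns <- length(sol_idx)
  nf <- n_frames(cluster)
  coords <- array(NA_real_, c(ns + k * spa, 3L, nf))
  slot_ids <- matrix(NA_integer_, nf, max(k, 0L))
  assignment <- matrix(NA_character_, nf, max(k, 0L))
  src_ids <- if (!is.null(cluster$slot_ids)) cluster$slot_ids else
    matrix(rep(as.integer(names(groups)), each = nf), nf)
  clabs <- vapply(centers, `[[`, character(1), "label")
  for (f in seq_len(nf)) {
    xyz <- frame_coords(cluster, f)
    if (k > 0) {
      D <- center_solvent_distances(xyz, centers, groups, distance_mode)
      pick <- tryCatch(greedy_assign(D, n_retain),
                       error = function(e)
                         stop("frame ", f, ": ", conditionMessage(e),
                              call. = FALSE))
      sel <- unlist(pick, use.names = FALSE)
      slot_ids[f, ] <- src_ids[f, sel]
      assignment[f, ] <- rep(clabs, n_retain)
      coords[, , f] <- rbind(xyz[sol_idx, , drop = FALSE],
                             xyz[unlist(groups[sel], use.names = FALSE), ,
                                 drop = FALSE])
    } else {
      coords[, , f] <- xyz[sol_idx, , drop = FALSE]
    }
  }
  if (k > 0) {
    tmpl <- topo[groups[[1]], , drop = FALSE]
    sv_res <- max(topo$resno[sol_idx]) + seq_len(k)
    sv_topo <- do.call(rbind, lapply(seq_len(k), function(s) {
      b <- tmpl
      b$resno <- sv_res[s]
      b$molecule_id <- max(topo$molecule_id[sol_idx]) + s
      b
    }))
    new_topo <- rbind(topo[sol_idx, , drop = FALSE], sv_topo)
  } else new_topo <- topo[sol_idx, , drop = FALSE]
  rt <- trajectory(new_topo, coords)
  rt$k <- as.integer(k)
  rt$M <- as.integer(k)
  rt$slot_ids <- slot_ids
  rt$assignment <- assignment
  rt$provenance <- list(stage = "remcs", distance_mode = distance_mode,
                        centers = lapply(centers, unclass),
                        upstream = cluster$provenance)
  class(rt) <- c("reduced_cluster_trajectory", "cluster_trajectory",
                 "trajectory")
  rt
}

#' Suggest candidate aggregation centers from a topology
#'
#' Advisory heuristic: solute N, O and S atoms (the usual hydrogen-bonding
#' aggregation sites) grouped into chemical groups by shared base name and
#' residue; \code{n_retain} is left at 0 for the user to set.
#'
#' @param topology a trajectory topology data.frame.
#' @return list of \code{\link{aggregation_center}} (possibly empty).
#' @export
suggest_centers <- function(topology) {
  sel <- topology$role == "solute" & topology$element %in% c("N", "O", "S")
  if (!any(sel)) return(list())
  idx <- which(sel)
  # group by element + alphabetic stem of the atom name (O/OXT -> one
  # carboxylate-like group; N -> amino group)
  stem <- substr(gsub("[0-9]", "", topology$name[idx]), 1, 1)
  key <- paste(topology$element[idx], stem, topology$resno[idx])
  grp <- split(idx, factor(key, levels = unique(key)))
  lapply(seq_along(grp), function(i)
    aggregation_center(grp[[i]], 0L, names(grp)[i]))
}
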