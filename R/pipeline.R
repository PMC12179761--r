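# End-to-end pipeline driver: chains trajectory input -> EMCS -> rEMCS -> ED
# -> landscape/basins (-> constraint specs -> weighted spectrum), writing
# per-stage artifacts, a JSON run report and the resolved configuration.
# Stages communicate via files under the output directory, so a run is
# restartable and has no hidden state.

resolve_center_atoms <- function(atoms, topology) {
  if (is.numeric(atoms)) return(as.integer(atoms))
  idx <- which(topology$role == "solute" & topology$name %in% atoms)
  if (!length(idx))
    stop("invalid center selection: no solute atom named ",
         paste(atoms, collapse = "/"))
  idx
}

#' Run the cluster-extraction pipeline from a configuration
#'
#' Executes, in order, the stages present in \code{config}: trajectory input
#' (\code{trajectory}: path + \code{format} + \code{solvent}, or
#' \code{synthetic}: arguments of \code{\link{synthetic_spec}}), \code{emcs}
#' (\code{padding}, \code{scale}, \code{statistic}, optional fixed \code{M}),
#' \code{remcs} (\code{centers}: list of \code{label}/\code{atoms}/\code{n}),
#' \code{ed} (\code{variance_fraction}), \code{basins} (\code{dims},
#' \code{n_bins}, \code{temperature_K}, \code{g_cut}, \code{min_depth},
#' \code{renormalize}), optional \code{convergence} (\code{n_splits}),
#' optional \code{constraints} and optional \code{spectrum} (\code{sticks}
#' file list or generated, \code{weights}, \code{bandwidth}, \code{range},
#' optional \code{reference} file). Frame counts at every reduction step
#' (N -> M -> k) are logged.
#'
#' @param config a named list or the path of a YAML config file.
#' @param out_dir artifact directory (created if absent).
#' @return (invisibly) a list with the stage objects and the report; artifacts
#'   (resolved config, JSON report, representative structures, landscape and
#'   spectrum tables, log) are written under \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir = "remcs_run") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)
  res <- list()
  report <- list()

  stage <- "input"
  out <- tryCatch({
    traj <- if (!is.null(config$synthetic)) {
      spec <- do.call(synthetic_spec, config$synthetic)
      generate_trajectory(spec)
    } else if (!is.null(config$trajectory)) {
      read_trajectory(config$trajectory,
                      format = config$format,
                      solvent = as.character(config$solvent %||% character(0)))
    } else if (is.null(config$spectrum)) {
      # a spectrum-only run needs no trajectory input
      stop("config needs a 'trajectory' path or a 'synthetic' block")
    } else NULL
    if (!is.null(traj)) {
      res$trajectory <- traj
      log_line("input: %d frames, N = %d solvent molecules", n_frames(traj),
               n_solvent(traj))
    }

    cluster <- traj
    if (!is.null(config$emcs)) {
      stage <- "emcs"
      e <- config$emcs
      M <- if (!is.null(e$M)) as.integer(e$M) else
        determine_M(traj, padding = e$padding %||% 3.0,
                    scale = e$scale %||% 1.0,
                    statistic = e$statistic %||% "median")
      cluster <- emcs_extract(traj, M, padding = e$padding %||% 3.0,
                              scale = e$scale %||% 1.0)
      res$emcs <- cluster
      report$M <- as.integer(M)
      log_line("emcs: N = %d -> M = %d", n_solvent(traj), M)
    }

    if (!is.null(config$remcs)) {
      stage <- "remcs"
      centers <- lapply(config$remcs$centers, function(ce)
        aggregation_center(resolve_center_atoms(ce$atoms, cluster$topology),
                           ce$n, ce$label))
      cluster <- remcs_reduce(cluster, centers,
                              distance_mode =
                                config$remcs$distance_mode %||% "nearest_atom")
      res$remcs <- cluster
      report$k <- cluster$k
      log_line("remcs: M = %d -> k = %d", report$M %||% n_solvent(traj),
               cluster$k)
    }

    ed <- NULL; bs <- NULL
    if (!is.null(config$ed) || !is.null(config$basins)) {
      stage <- "ed"
      ed <- ed_analyze(cluster)
      res$ed <- ed
      vf <- (config$ed$variance_fraction) %||% 0.6
      report$essential_eigenvectors <- essential_count(ed, vf)
      tot <- sum(ed$eigenvalues)
      report$eigenvalue_fractions <-
        as.numeric(utils::head(ed$eigenvalues / tot, 5))
      log_line("ed: %d essential eigenvectors at %.0f%% variance",
               report$essential_eigenvectors, 100 * vf)
    }
    if (!is.null(config$basins)) {
      stage <- "basins"
      b <- config$basins
      fel <- build_landscape(ed, dims = b$dims %||% 1:2,
                             n_bins = b$n_bins %||% 64,
                             temperature_K = b$temperature_K %||% 300)
      bs <- detect_basins(fel, g_cut = b$g_cut %||% 4,
                          min_depth = b$min_depth %||% 1,
                          renormalize = isTRUE(b$renormalize))
      res$landscape <- fel; res$basins <- bs
      write_landscape(fel, file.path(out_dir, "landscape.txt"))
      report$basin_weights <- as.numeric(bs$basins$probability)
      report$retained_fraction <- bs$retained_fraction
      log_line("basins: %d basin(s), weights %s", nrow(bs$basins),
               paste(signif(bs$basins$probability, 3), collapse = ", "))
      # representative structures for the QM hand-off
      for (i in seq_len(nrow(bs$basins))) {
        fr <- bs$basins$representative_frame[i]
        rep1 <- trajectory(cluster$topology, cluster$coords[, , fr])
        write_trajectory(rep1, file.path(out_dir,
                                         sprintf("representative_%s.pdb",
                                                 bs$basins$label[i])))
      }
      if (!is.null(config$convergence)) {
        stage <- "convergence"
        cv <- convergence_check(cluster,
                                n_splits = config$convergence$n_splits %||% 3,
                                dims = b$dims %||% 1:2,
                                n_bins = b$n_bins %||% 64,
                                g_cut = b$g_cut %||% 4,
                                min_depth = b$min_depth %||% 1)
        res$convergence <- cv
        report$convergence_max_deviation <- cv$max_deviation
        log_line("convergence: max basin-weight deviation %.4f over %d splits",
                 cv$max_deviation, config$convergence$n_splits %||% 3)
      }
      if (!is.null(config$constraints)) {
        stage <- "constraints"
        for (i in seq_len(nrow(bs$basins))) {
          cs <- build_constraints(cluster, bs$basins$representative_frame[i],
                                  solute_torsions =
                                    config$constraints$solute_torsions %||% list(),
                                  solvent_torsions =
                                    config$constraints$solvent_torsions %||% list())
          write_constraints(cs, file.path(out_dir,
                                          sprintf("constraints_%s.txt",
                                                  bs$basins$label[i])))
        }
      }
    }

    if (!is.null(config$spectrum)) {
      stage <- "spectrum"
      sp <- config$spectrum
      sticks <- lapply(sp$sticks, parse_sticks)
      w <- if (!is.null(sp$weights)) as.numeric(sp$weights)
           else if (!is.null(bs)) bs$basins$probability[seq_along(sticks)]
           else rep(1 / length(sticks), length(sticks))
      bw <- sp$bandwidth %||% 7.0
      lo <- min(vapply(sticks, function(s) min(s$lines$wavenumber), 1))
      hi <- max(vapply(sticks, function(s) max(s$lines$wavenumber), 1))
      grid <- seq(floor(lo - 4 * bw), ceiling(hi + 4 * bw), by = 1)
      spectra <- lapply(sticks, broaden, bandwidth = bw, grid = grid)
      comp <- normalize_spectrum(assemble_spectra(spectra, w))
      res$spectrum <- comp
      write_spectrum(comp, file.path(out_dir, "spectrum.txt"))
      if (!is.null(sp$reference)) {
        ref <- utils::read.table(sp$reference, header = FALSE,
                                 comment.char = "#")
        refsp <- new_spectrum(ref[[1]], ref[[2]])
        rng <- if (!is.null(sp$range)) as.numeric(sp$range) else NULL
        report$spectrum_rmsd <- spectrum_rmsd(comp, refsp, rng)
        log_line("spectrum: RMSD vs reference %.3f", report$spectrum_rmsd)
      }
      log_line("spectrum: %d conformers, bandwidth %.1f cm^-1",
               length(sticks), bw)
    }
    res
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  report$version <- as.character(utils::packageVersion("remcs"))
  yaml::write_yaml(config, file.path(out_dir, "config.yml"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  out$report <- report
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
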