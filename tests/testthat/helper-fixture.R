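# Shared study fixture: the full-scale synthetic run used by the recovery,
# steepening and convergence tests. Built once per test session and cached;
# all parameters are the package defaults plus the study conditions (50,000
# frames, seed 42, M = 10 solvent slots, the canonical alanine centers).

.study_cache <- new.env(parent = emptyenv())

study_fixture <- function() {
  if (is.null(.study_cache$fx)) {
    spec <- synthetic_spec(n_frames = 50000L, seed = 42L)
    traj <- generate_trajectory(spec)
    labels <- attr(traj, "labels")
    cluster <- emcs_extract(traj, M = 10L)
    rm(traj)
    reduced <- remcs_reduce(cluster, alanine_centers(cluster$topology))
    ed <- ed_analyze(reduced)
    fel <- build_landscape(ed)
    basins <- detect_basins(fel, renormalize = TRUE)
    .study_cache$fx <- list(spec = spec, labels = labels,
                            truth = spec$weights, cluster = cluster,
                            reduced = reduced, ed = ed, fel = fel,
                            basins = basins)
  }
  .study_cache$fx
}
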