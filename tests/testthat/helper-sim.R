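# shared small simulation fixtures, built in code at test time

small_movie <- function(seed = 11, n_founders = 6, duration = 30, ...) {
  simulate_lineages(sim_config(n_founders = n_founders, duration = duration,
                               seed = seed, ...))
}

tracked_forest <- function(sim, params = link_params()) {
  tr <- track_cells(sim$obs, params)
  dv <- suppressWarnings(detect_divisions(tr, params))
  build_lineages(tr, dv)
}

# archetype foci traces (30-min frames)
trace_endo <- function() c(rep(1, 4), rep(20, 16), rep(1, 6), rep(25, 16),
                           rep(1, 3))
trace_rere <- function() c(rep(1, 4), rep(20, 40), rep(1, 2))
trace_normal <- function() c(rep(1, 6), rep(20, 16), rep(1, 8))
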