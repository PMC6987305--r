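# Shared fixtures and memoized simulation experiments.

# Small culture used by several engine tests.
small_topology <- function(seed = 3, n_astro = 8) {
  build_culture_topology(n_neurons = 40, n_excitatory = 32,
                         n_astrocytes = n_astro, seed = seed)
}

# A two-neuron, one-synapse, one-astrocyte tripartite fixture built by hand:
# excitatory neuron 1 projects to neuron 2; the astrocyte sits 20 um from the
# postsynaptic soma, well inside the enwrapping cutoff.
tripartite_topology <- function(y_base = 0.35, enwrapped = TRUE) {
  geometry <- culture_geometry()
  structure(list(
    neuron_positions = rbind(c(100, 100, 5), c(150, 100, 5)),
    is_excitatory = c(TRUE, TRUE),
    c_unit = c(1, 0),
    synapses = data.frame(pre = 1L, post = 2L, y_base = y_base, sign = 1,
                          distance = 50,
                          astrocyte = if (enwrapped) 1L else NA_integer_),
    astro_positions = matrix(c(150, 120, 5), nrow = 1),
    gap = build_gap_junctions(matrix(c(150, 120, 5), nrow = 1),
                              geometry$gap_cutoff),
    geometry = geometry,
    synapse_site = "post"), class = "culture_topology")
}

# Memoized experiments shared across acceptance blocks (run once per suite).
.experiment_cache <- new.env(parent = emptyenv())

cached_experiment <- function(scenario, C_max, n_astro, seed,
                              T_total = 60, n_runs = 2) {
  key <- paste(scenario, C_max, n_astro, seed, T_total, n_runs, sep = "_")
  if (!is.null(.experiment_cache[[key]])) return(.experiment_cache[[key]])
  cfg <- build_scenario(scenario, C_max, n_astro, n_runs = n_runs,
                        params = inexa_params(T_total = T_total))
  ex <- run_experiment(cfg, seed = seed)
  .experiment_cache[[key]] <- ex
  ex
}
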