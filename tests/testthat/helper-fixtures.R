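# Shared fixtures: a desk-scale engine configuration for fast engine tests
# (smaller founder cohort and shorter reaction than the defaults) and a
# cache so expensive runs are computed once per test session.

fast_engine <- function(duration = 240, n_founders = 40, seed = 1L, ...) {
  engine_config(duration = duration, n_founders = n_founders,
                seed = seed, ...)
}

run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (is.null(run_cache[[key]])) run_cache[[key]] <- force(expr)
  run_cache[[key]]
}

# numerical max-norm of the network rates at a state
rhs_norm <- function(state, params = grn_parameters()) {
  max(abs(grn_rhs(state, params, signal_input())))
}
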