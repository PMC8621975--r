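# Shared fixtures: tiny networks, deterministic random models, and a cache
# so expensive scenario runs are computed once per test session.

uni_uni_network <- function() {
  S <- matrix(c(-1L, 1L), 2, 1, dimnames = list(c("A", "B"), "R1"))
  mb_network(S, is_internal = c(FALSE, FALSE))
}

# Basic vector for a uni-uni network with prescribed constants
uni_uni_basic <- function(schema, ln_keq = 0, ln_km_s = 0, ln_km_p = 0,
                          ln_kv = 0) {
  q <- numeric(schema$n_basic)
  q[schema$idx_g] <- c(ln_keq, 0)
  q[schema$idx_km] <- c(ln_km_s, ln_km_p)
  q[schema$idx_kv] <- ln_kv
  q
}

# Random chain model of n reactions with a feasible one-state flux vector
# and a valid interior point; deterministic in seed.
random_chain_problem <- function(n_reactions, n_states = 1, seed = 1,
                                 alpha = 0, with_data = TRUE) {
  net <- example_network("chain", n_reactions)
  ds <- make_scenario_dataset(net, if (with_data) "S1K" else "S2",
                              n_states = n_states, state_gsd = 1.2,
                              kinetic_gsd = 1.5, seed = seed)
  mb_problem(net, ds$fluxes, ds$data, alpha = alpha,
             options = mb_options(seed = seed))
}

# Session cache for expensive scenario runs shared between tests
.mb_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .mb_cache)) {
    val <- expr
    if (is.null(val)) return(NULL)
    assign(key, val, envir = .mb_cache)
  }
  get(key, envir = .mb_cache)
}

# Small noisy S1K run reused by several test files
get_s1k_small <- function() {
  cached("s1k_small", {
    net <- example_network("chain", 3)
    ds <- make_scenario_dataset(net, "S1K", n_states = 2, state_gsd = 1.2,
                                kinetic_gsd = 1.5, seed = 23)
    prob <- mb_problem(net, ds$fluxes, ds$data, alpha = 0.5)
    list(ds = ds, prob = prob, res = balance(prob))
  })
}

# Scenario run helper: generate + balance + report
run_scenario <- function(scenario, seed, state_gsd = 1, kinetic_gsd = 1,
                         n_reactions = 5, n_states = 6, alpha = 0.5) {
  net <- example_network("chain", n_reactions)
  ds <- make_scenario_dataset(net, scenario, n_states = n_states,
                              state_gsd = state_gsd,
                              kinetic_gsd = kinetic_gsd, seed = seed)
  prob <- mb_problem(net, ds$fluxes, ds$data, alpha = alpha,
                     options = mb_options(seed = seed))
  res <- balance(prob)
  list(dataset = ds, problem = prob, result = res,
       report = build_report(ds$truth, res, scenario))
}

metric_of <- function(report, quantity, field = "r_log") {
  report$metrics[report$metrics$quantity == quantity, field]
}
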