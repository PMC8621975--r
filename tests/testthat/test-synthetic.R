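test_that("true-model draws are reproducible and reach the catalogue targets", {
  net <- example_network("chain", 3)
  a <- sample_true_model(net, seed = 5)
  b <- sample_true_model(net, seed = 5)
  expect_identical(a$q_basic, b$q_basic)
  expect_false(identical(a$q_basic, sample_true_model(net, seed = 6)$q_basic))
  # marginal of the KM draws: geometric mean 0.1 mM, gsd 10 (law of large
  # numbers over 10 000 KM entries from a long chain)
  long <- example_network("chain", 100)
  sch <- build_schema(long)
  kms <- unlist(lapply(1:50, function(s)
    sample_true_model(long, seed = s)$q_basic[sch$idx_km]))
  expect_gte(length(kms), 10000)
  gm <- exp(mean(kms))
  expect_lt(abs(gm - 0.1) / 0.1, 0.05)
  gsd <- exp(sd(kms))
  expect_lt(abs(gsd - 10) / 10, 0.05)
  # draws are Wegscheider-consistent by construction
  for (s in 1:20)
    expect_lt(check_wegscheider(
      sample_true_model(net, seed = s)$constants$ln_Keq, net), 1e-10)
})

test_that("multiplicative noise has the requested geometric spread", {
  expect_identical(add_noise(c(1, 2, 3), 1), c(1, 2, 3))
  x <- add_noise(rep(1, 10000), 1.2, seed = 8)
  expect_lt(abs(exp(sd(log(x))) - 1.2) / 1.2, 0.02)
  expect_identical(add_noise(rep(1, 10), 1.5, seed = 3),
                   add_noise(rep(1, 10), 1.5, seed = 3))
  expect_error(add_noise(1, 0.9), ">= 1")
})

test_that("steady states satisfy stationarity and flux conservation", {
  net <- example_network("chain", 2)
  sch <- build_schema(net)
  # strongly forward constants: near-complete conversion, v1 = v2
  q <- numeric(sch$n_basic)
  q[sch$idx_g] <- c(12, 6, 0)
  q[sch$idx_km] <- log(0.1)
  q[sch$idx_kv] <- log(10)
  cst <- expand_constants(sch, q)
  ss <- simulate_steady_state(net, cst, c(1e-3, 1e-3), c(log(1), log(0.01)))
  expect_true(ss$converged)
  expect_equal(ss$v[1], ss$v[2], tolerance = 1e-6)
  expect_gt(ss$v[1], 0)
  # stationarity residual on random models
  set.seed(19)
  n_ok <- 0
  for (rep in 1:20) {
    tm <- sample_true_model(net, seed = 300 + rep)
    e <- exp(rnorm(2, log(1e-3), log(10)))
    xe <- rnorm(2, log(0.1), log(10))
    ss <- simulate_steady_state(net, tm$constants, e, xe)
    if (!ss$converged) next
    S_int <- net$S[net$is_internal, , drop = FALSE]
    expect_lt(max(abs(S_int %*% ss$v)), 1e-8 * max(abs(ss$v), 1e-12))
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 10)
})

test_that("reported steady states are fixed points of an independent integrator", {
  # oracle: fixed-step RK4 in linear concentration space, started AT the
  # reported state; a true steady state must not drift
  net <- example_network("chain", 3)
  n_checked <- 0
  for (s in 1:6) {
    tm <- sample_true_model(net, seed = 400 + s)
    set.seed(500 + s)
    e <- exp(rnorm(3, log(1e-3), log(10)))
    xe <- rnorm(2, log(0.1), log(10))
    ss <- simulate_steady_state(net, tm$constants, e, xe)
    if (!ss$converged) next
    int <- which(net$is_internal)
    rate <- modelbalance:::make_rate_fn(tm$constants, e)
    x <- ss$x
    f <- function(c_int) {
      x[int] <- log(c_int)
      unname(drop(net$S[int, , drop = FALSE] %*% rate(x)))
    }
    c0 <- exp(unname(ss$x[int]))
    # stability-limited step from a crude Jacobian norm estimate
    J0 <- vapply(seq_along(c0), function(j) {
      cp <- c0; cp[j] <- cp[j] * 1.001
      max(abs((f(cp) - f(c0)) / (0.001 * c0[j])))
    }, 0)
    h <- min(1, 0.5 / max(J0, 1e-6))
    c_int <- c0
    for (step in 1:5000) {
      k1 <- f(c_int); k2 <- f(pmax(c_int + h / 2 * k1, 1e-15))
      k3 <- f(pmax(c_int + h / 2 * k2, 1e-15))
      k4 <- f(pmax(c_int + h * k3, 1e-15))
      c_int <- pmax(c_int + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 1e-15)
    }
    expect_equal(log(c_int), log(c0), tolerance = 1e-6)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 2)
})

test_that("scenario datasets respect their filtering contracts", {
  net <- example_network("chain", 3)
  kin_types <- c("equilibrium constant", "catalytic rate constant (forward)",
                 "catalytic rate constant (backward)", "Michaelis constant")
  ds1 <- make_scenario_dataset(net, "S1", n_states = 2, seed = 2)
  ds1k <- make_scenario_dataset(net, "S1K", n_states = 2, seed = 2)
  ds2 <- make_scenario_dataset(net, "S2", n_states = 2, seed = 2)
  expect_equal(sum(ds2$data$QuantityType %in% kin_types), 0)
  expect_equal(sum(ds1k$data$QuantityType %in% kin_types), ncol(net$S))
  expect_true(all(ds1k$data$QuantityType[ds1k$data$QuantityType %in%
                                           kin_types] ==
                    "equilibrium constant"))
  n_pairs <- nrow(build_schema(net)$pairs)
  expect_equal(sum(ds1$data$QuantityType %in% kin_types),
               2 * ncol(net$S) + ncol(net$S) + n_pairs)
  # noise-free variant carries the exact truth values
  keq_rows <- ds1$data$QuantityType == "equilibrium constant"
  expect_equal(sort(log(ds1$data$Mean[keq_rows])),
               sort(unname(ds1$truth$constants$ln_Keq)), tolerance = 1e-12)
  # reproducibility of the whole bundle
  ds1b <- make_scenario_dataset(net, "S1", n_states = 2, seed = 2)
  expect_identical(ds1$truth, ds1b$truth)
  expect_identical(ds1$data, ds1b$data)
})

test_that("generated truths are strictly inside the default polytope", {
  net <- example_network("branch", 4)
  ds <- make_scenario_dataset(net, "S2", n_states = 3, seed = 44)
  sch <- build_schema(net)
  prob <- mb_problem(net, ds$fluxes, ds$data)
  y_true <- c(ds$truth$q_basic, as.vector(ds$truth$x))
  expect_gte(polytope_margin(prob$polytope, y_true), 0)
  # force signs match the generated fluxes
  expect_true(all(sign(ds$truth$theta) == sign(ds$truth$v)))
})
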