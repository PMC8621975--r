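test_that("initialisation returns the preposterior mean when it is interior", {
  net <- example_network("chain", 2)
  # strong Keq data and concentration data put the mean strictly inside
  dat <- rbind(
    mb_data("equilibrium constant", c("R1", "R2"), NA, NA, 100, 1.01),
    mb_data("concentration", NA, "Xin", 1, 1, 1.01),
    mb_data("concentration", NA, "M1", 1, 0.1, 1.01),
    mb_data("concentration", NA, "Xout", 1, 0.01, 1.01))
  prob <- mb_problem(net, matrix(c(1e-3, 1e-3), 2, 1), dat)
  y0 <- initialize_balancing(prob)
  lay <- prob$polytope$layout
  target <- c(prob$prepost$q_mean, prob$prepost$x_mean[, 1])
  expect_equal(y0, target, tolerance = 1e-12)
  expect_gt(polytope_margin(prob$polytope, y0), 0)
})

test_that("an infeasible mean is projected with minimal displacement", {
  # with no data the prior mean has theta = 0 everywhere, violating the
  # force margin, so a projection must run; optimality of the projection is
  # verified by the KKT condition: the displacement lies in the cone of
  # active constraint normals
  net <- example_network("chain", 3)
  prob <- mb_problem(net, matrix(1e-3, 3, 1))
  y0 <- initialize_balancing(prob)
  poly <- prob$polytope
  expect_gte(polytope_margin(poly, y0), 0)
  target <- c(prob$prepost$q_mean, prob$prepost$x_mean[, 1])
  d <- y0 - target
  margins <- drop(poly$ui %*% y0) - poly$ci
  A <- poly$ui[margins < 1e-4, , drop = FALSE]
  # nonnegative least squares by projected coordinate sweeps
  lam <- numeric(nrow(A)); resid <- d
  for (sw in 1:200) for (i in seq_len(nrow(A))) {
    step <- sum(A[i, ] * resid) / sum(A[i, ]^2)
    new <- max(0, lam[i] + step)
    resid <- resid - (new - lam[i]) * A[i, ]
    lam[i] <- new
  }
  expect_lt(sqrt(sum(resid^2)), 1e-3 * max(1, sqrt(sum(d^2))))
})

test_that("an empty feasible set raises an error", {
  net <- example_network("chain", 2)
  b <- mb_bounds(g_abs_max = 0.1,
                 conc_overrides = list(Xin = c(1e-6, 1.1e-6),
                                       Xout = c(90, 100)))
  expect_error(mb_problem(net, matrix(c(1e-3, 1e-3), 2, 1), bounds = b),
               "infeasible")
  expect_error(mb_bounds(conc_min = 10, conc_max = 1), "conc_min > conc_max")
})

test_that("balancing beats both the start and the generating truth in score", {
  sc <- get_s1k_small()
  prob <- sc$prob; ds <- sc$ds; res <- sc$res
  expect_true(res$diagnostics$converged)
  expect_gte(res$diagnostics$polytope_margin, 0)
  y0 <- initialize_balancing(prob)
  expect_lte(res$total, assemble_posterior_score(prob, y0)$total + 1e-8)
  y_true <- c(ds$truth$q_basic, as.vector(ds$truth$x))
  expect_lte(res$total, assemble_posterior_score(prob, y_true)$total + 1e-8)
  # the optimum satisfies stationarity
  expect_lt(res$diagnostics$kkt_residual, 1e-2)
})

test_that("zero-flux reactions are dropped from scoring and results", {
  net <- example_network("chain", 3)
  V <- matrix(c(1e-3, 0, 1e-3), 3, 1)   # non-stationary snapshot state
  dat <- rbind(
    mb_data("enzyme concentration", c("R1", "R2", "R3"), NA, 1,
            c(2e-3, 5e-3, 1e-3), 1.2),
    mb_data("concentration", NA, net$metabolite_ids, 1, 0.2, 1.2))
  prob_with <- mb_problem(net, V, dat, alpha = 0.5)
  prob_without <- mb_problem(net, V, dat[dat$Reaction != "R2" |
                                           is.na(dat$Reaction), ],
                             alpha = 0.5)
  r1 <- balance(prob_with); r2 <- balance(prob_without)
  # the R2 enzyme estimate is absent (NA), not zero
  expect_true(is.na(r1$z["R2", 1]))
  expect_false(anyNA(r1$z[c("R1", "R3"), 1]))
  # and the ignored datum changes nothing
  expect_equal(r1$y_star, r2$y_star, tolerance = 1e-8)
})

test_that("maximum-likelihood mode tracks balance when data are abundant", {
  net <- example_network("chain", 3)
  ds <- cached("s1_ml", make_scenario_dataset(net, "S1", n_states = 3,
                                              seed = 31))
  prob <- mb_problem(net, ds$fluxes, ds$data, alpha = 0.5)
  res <- balance(prob)
  ml <- maximum_likelihood_mode(prob)
  expect_false(isTRUE(ml$diagnostics$prior_insensitive))
  expect_lt(max(abs(ml$y_star - res$y_star)), 0.2)
  # with no data at all the run is flagged prior-insensitive
  prob0 <- mb_problem(net, ds$fluxes, NULL, alpha = 0.5)
  ml0 <- maximum_likelihood_mode(prob0)
  expect_true(ml0$diagnostics$prior_insensitive)
})

test_that("flat priors move data-free quantities most", {
  net <- example_network("chain", 3)
  ds <- cached("s1k_ml", make_scenario_dataset(net, "S1K", n_states = 3,
                                               seed = 37))
  prob <- mb_problem(net, ds$fluxes, ds$data, alpha = 0.5)
  res <- balance(prob)
  ml <- maximum_likelihood_mode(prob)
  sch <- prob$schema
  move <- abs(ml$y_star - res$y_star)
  # Keq is data-backed (S1K); KM has no data and rides on the prior
  keq_move <- max(abs(ml$constants$ln_Keq - res$constants$ln_Keq))
  km_move <- max(move[sch$idx_km])
  expect_lt(keq_move, km_move)
})

test_that("no data yields a plausible prior-driven state", {
  # with no data the method still predicts a feasible state near the prior
  # means (the displacement comes only from the force-sign constraints and
  # the enzyme prior term)
  net <- example_network("chain", 2)
  pri <- prior_catalogue(enzyme_gsd = exp(30))   # flatten the enzyme pull
  prob <- mb_problem(net, matrix(c(2e-3, 2e-3), 2, 1), priors = pri,
                     alpha = 0.5)
  res <- balance(prob)
  target <- c(prob$prepost$q_mean, prob$prepost$x_mean[, 1])
  expect_gte(res$diagnostics$polytope_margin, 0)
  expect_lt(max(abs(res$y_star - target)), 1)
  # and the optimum is no worse than the projected prior mean
  y0 <- initialize_balancing(prob)
  expect_lte(res$total, assemble_posterior_score(prob, y0)$total + 1e-8)
  # optimality of the precision-weighted fit: the quadratic-score gradient
  # at the optimum is supported on active constraint normals
  expect_lt(res$diagnostics$kkt_residual, 1e-2)
})

test_that("adding an exact datum does not worsen that quantity's recovery", {
  # statistical monotone-data-effect check: over 20 noise-free repeats, an
  # exact Michaelis-constant datum never (allowing one tolerance-level
  # violation) increases the error of that constant's estimate
  net <- example_network("chain", 3)
  sch <- build_schema(net)
  worse <- 0; n_rep <- 20
  for (rep in seq_len(n_rep)) {
    ds <- make_scenario_dataset(net, "S2", n_states = 1, seed = 100 + rep)
    true_km <- exp(ds$truth$constants$ln_KM[1])
    pair <- sch$pairs[1, ]
    extra <- mb_data("Michaelis constant", net$reaction_ids[pair$reaction],
                     net$metabolite_ids[pair$metabolite], NA, true_km, 1.01)
    e0 <- abs(balance(mb_problem(net, ds$fluxes, ds$data, alpha = 0.5)
                      )$constants$ln_KM[1] - log(true_km))
    e1 <- abs(balance(mb_problem(net, ds$fluxes, rbind(ds$data, extra),
                                 alpha = 0.5))$constants$ln_KM[1] -
                log(true_km))
    if (e1 > e0 + 1e-6) worse <- worse + 1
  }
  expect_lte(worse, ceiling(0.05 * n_rep))
})

test_that("fixed coordinates are honoured and validated", {
  net <- example_network("chain", 2)
  sch <- build_schema(net)
  fx <- c(6, 3, 0, rep(log(0.1), 4), log(10), log(10))
  names(fx) <- sch$basic_names
  prob <- mb_problem(net, matrix(c(1e-3, 1e-3), 2, 1), fixed = fx)
  res <- balance(prob)
  expect_equal(unname(res$y_star[seq_along(fx)]), unname(fx))
  expect_error(mb_problem(net, matrix(c(1e-3, 1e-3), 2, 1),
                          fixed = c(nosuch = 1)), "unknown fixed")
})
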