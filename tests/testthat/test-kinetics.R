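test_that("CM rate law reproduces the reversible Michaelis-Menten values", {
  net <- uni_uni_network()
  sch <- build_schema(net)
  # kcat+ = 2, kcat- = 1, KM = 1 both sides (Haldane fixes ln Keq = ln 2)
  q <- uni_uni_basic(sch, ln_keq = log(2), ln_kv = log(2) / 2)
  cst <- expand_constants(sch, q)
  expect_equal(exp(unname(cst$ln_kcat_fwd)), 2)
  expect_equal(exp(unname(cst$ln_kcat_bwd)), 1)
  # s/Ks = p/Kp = 1: k = (2 - 1) / 3
  expect_equal(catalytic_rate_cm(cst, c(0, 0), 1), 1 / 3)
  # saturation limit: s >> Ks, p -> 0
  expect_equal(catalytic_rate_cm(cst, c(30, -30), 1), 2, tolerance = 1e-9)
  # equilibrium concentrations: theta = 0 gives k = 0
  x_eq <- c(0, log(2))   # t(S) x = ln Keq
  expect_equal(catalytic_rate_cm(cst, x_eq, 1), 0, tolerance = 1e-12)
})

test_that("efficiency factors take their textbook values", {
  expect_equal(eta_rev(0), 0)
  expect_equal(eta_rev(log(2)), 0.5)
  expect_equal(eta_rev(1e4), 1)
  net <- uni_uni_network()
  sch <- build_schema(net)
  cst <- expand_constants(sch, uni_uni_basic(sch, ln_keq = log(2),
                                             ln_kv = log(2) / 2))
  expect_equal(eta_sat(cst, c(0, 0), 1), 1 / 3)
  expect_equal(eta_sat(cst, c(30, -30), 1), 1, tolerance = 1e-9)
  expect_lt(eta_sat(cst, c(-20, -20), 1), 1e-8)
})

test_that("factorisation k = kcat+ eta_rev eta_sat holds on random draws", {
  set.seed(21)
  nets <- list(uni_uni_network(), example_network("chain", 3),
               example_network("triangle"))
  n_checked <- 0
  for (net in nets) {
    sch <- build_schema(net)
    for (rep in seq_len(ceiling(1000 / length(nets) / ncol(net$S)))) {
      q <- rnorm(sch$n_basic, 0, 2)
      cst <- expand_constants(sch, q)
      x <- rnorm(nrow(net$S), log(0.1), 2)
      th <- driving_forces(cst$ln_Keq, net$S, x)
      for (l in seq_len(ncol(net$S))) {
        k <- catalytic_rate_cm(cst, x, l)
        expect_equal(sign(k), sign(th[l]))
        sg <- sign(th[l])
        kcat <- if (sg >= 0) exp(cst$ln_kcat_fwd[[l]]) else exp(cst$ln_kcat_bwd[[l]])
        kf <- sg * kcat * eta_rev(abs(th[l])) * eta_sat(cst, x, l, sg)
        expect_equal(k, kf, tolerance = 1e-10)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gte(n_checked, 1000)
})

test_that("enzyme demand is flux over rate with strict sign checking", {
  expect_equal(enzyme_demand(1, 1 / 3), 3)
  expect_equal(enzyme_demand(2, 1 / 3), 6)
  expect_error(enzyme_demand(1, -1), "sign")
  expect_error(enzyme_demand(0, 1), "zero flux")
})

test_that("log enzyme demand gradient matches central differences", {
  set.seed(31)
  net <- example_network("chain", 3)
  sch <- build_schema(net)
  V <- matrix(c(1, 1, 1, -2, -2, -2), 3, 2) * 1e-3
  poly <- build_polytope(net, sch, V)
  lay <- poly$layout
  centre <- modelbalance:::polytope_centre(poly)
  rc <- list(ui = poly$ui, ci = poly$ci)
  for (rep in 1:50) {
    y <- modelbalance:::random_interior_point(rc, centre, poly$lower,
                                              poly$upper)
    s <- sample(1:2, 1)
    ze <- log_enzyme_demand_and_gradient(sch, y, V, s, lay)
    h <- 1e-6
    jcols <- sample(lay$n_y, 4)
    for (j in jcols) {
      yp <- y; yp[j] <- yp[j] + h
      ym <- y; ym[j] <- ym[j] - h
      fd <- (log_enzyme_demand_and_gradient(sch, yp, V, s, lay)$z -
               log_enzyme_demand_and_gradient(sch, ym, V, s, lay)$z) / (2 * h)
      expect_equal(ze$J[, j], fd, tolerance = 1e-5)
    }
  }
})

test_that("log enzyme demand is midpoint-convex on feasible pairs", {
  set.seed(41)
  net <- example_network("chain", 3)
  sch <- build_schema(net)
  V <- matrix(1e-3, 3, 1)
  poly <- build_polytope(net, sch, V)
  centre <- modelbalance:::polytope_centre(poly)
  rc <- list(ui = poly$ui, ci = poly$ci)
  for (rep in 1:200) {
    y1 <- modelbalance:::random_interior_point(rc, centre, poly$lower, poly$upper)
    y2 <- modelbalance:::random_interior_point(rc, centre, poly$lower, poly$upper)
    zm <- log_enzyme_demand_and_gradient(sch, (y1 + y2) / 2, V, 1)$z
    z1 <- log_enzyme_demand_and_gradient(sch, y1, V, 1)$z
    z2 <- log_enzyme_demand_and_gradient(sch, y2, V, 1)$z
    expect_true(all(zm <= (z1 + z2) / 2 + 1e-9))
  }
})

test_that("demand along one free metabolite is U-shaped (low then high)", {
  # one free metabolite between two reactions: demand of the consuming
  # reaction falls then rises as x sweeps the feasible interval
  net <- example_network("chain", 2)
  sch <- build_schema(net)
  q <- numeric(sch$n_basic)
  q[sch$idx_g] <- c(6, 3, 0)
  q[sch$idx_km] <- log(0.1)
  q[sch$idx_kv] <- log(10)
  V <- matrix(c(1e-3, 1e-3), 2, 1)
  poly <- build_polytope(net, sch, V)
  lay <- poly$layout
  y <- numeric(lay$n_y)
  y[lay$idx_q] <- q
  y[lay$idx_x[[1]]] <- c(0, log(0.1), log(0.01))
  iM <- match("x:M1:s1", lay$names)
  # theta > 0 for both reactions requires x_M1 in (-7.6, 3)
  grid <- seq(-7.5, 2.9, length.out = 200)
  ztot <- sapply(grid, function(xm) {
    y[iM] <- xm
    sum(log_enzyme_demand_and_gradient(sch, y, V, 1, lay)$z)
  })
  i0 <- which.min(ztot)
  expect_gt(i0, 1); expect_lt(i0, length(grid))
  expect_true(all(diff(ztot[seq_len(i0)]) <= 1e-9))
  expect_true(all(diff(ztot[i0:length(grid)]) >= -1e-9))
})
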