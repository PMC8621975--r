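# Synthetic-data generator: "true" kinetic constants drawn from the priors,
# steady states simulated from the kinetic model, and noisy data tables in
# the estimation scenarios S1 (all kinetic constants as data), S1K
# (equilibrium constants only), and S2 (no kinetic data).  State data carry
# geometric-standard-deviation 1.2 noise and kinetic data 1.5 in the noisy
# variants.

#' Prior catalogue for kinetic constants and concentrations
#'
#' Lognormal priors, given as linear-scale medians and geometric standard
#' deviations.  The per-metabolite term g (which sets ln Keq = -t(S) g) is
#' Gaussian with mean 0; its sd defaults to log(Keq gsd)/sqrt(2) so that a
#' uni-uni reaction's equilibrium constant has the catalogue's Keq gsd.
#'
#' @param Keq_median,Keq_gsd equilibrium constant (dimensionless)
#' @param kV_median,kV_gsd velocity constant (1/s)
#' @param KM_median,KM_gsd Michaelis constant (mM)
#' @param conc_median,conc_gsd metabolite concentration (mM)
#' @param enzyme_median,enzyme_gsd enzyme concentration (mM)
#' @param g_sd log-scale sd of g; derived from the Keq entry when NULL
#' @return a \code{prior_catalogue} list
#' @export
prior_catalogue <- function(Keq_median = 1, Keq_gsd = 10,
                            kV_median = 10, kV_gsd = 10,
                            KM_median = 0.1, KM_gsd = 10,
                            conc_median = 0.1, conc_gsd = 10,
                            enzyme_median = 1e-3, enzyme_gsd = 10,
                            g_sd = NULL) {
  meds <- c(Keq_median, kV_median, KM_median, conc_median, enzyme_median)
  gsds <- c(Keq_gsd, kV_gsd, KM_gsd, conc_gsd, enzyme_gsd)
  if (any(meds <= 0)) stopf("prior medians must be positive")
  if (any(gsds <= 1)) stopf("prior geometric standard deviations must be > 1")
  structure(list(
    Keq = list(median = Keq_median, gsd = Keq_gsd),
    kV = list(median = kV_median, gsd = kV_gsd),
    KM = list(median = KM_median, gsd = KM_gsd),
    conc = list(median = conc_median, gsd = conc_gsd),
    enzyme = list(median = enzyme_median, gsd = enzyme_gsd),
    g = list(mean = 0, sd = g_sd %||% (log(Keq_gsd) / sqrt(2)))
  ), class = "prior_catalogue")
}

#' Draw a ground-truth kinetic constant set from the priors
#'
#' Basic variables are drawn independently (g Gaussian, ln KM and ln kV from
#' the lognormal catalogue entries) and expanded through the dependency
#' schema, so the result satisfies Haldane and Wegscheider conditions by
#' construction.
#'
#' @param network an \code{\link{mb_network}}
#' @param priors a [prior_catalogue()]
#' @param seed RNG seed (reproducible draws)
#' @return list with \code{q_basic} and the expanded \code{constants}
#' @export
sample_true_model <- function(network, priors = prior_catalogue(), seed = 1) {
  set.seed(seed)
  schema <- build_schema(network)
  q <- numeric(schema$n_basic)
  q[schema$idx_g] <- stats::rnorm(length(schema$idx_g), priors$g$mean,
                                  priors$g$sd)
  q[schema$idx_km] <- stats::rnorm(length(schema$idx_km),
                                   log(priors$KM$median), log(priors$KM$gsd))
  q[schema$idx_kv] <- stats::rnorm(length(schema$idx_kv),
                                   log(priors$kV$median), log(priors$kV$gsd))
  list(q_basic = q, constants = expand_constants(schema, q), schema = schema)
}

#' Simulate a steady state of the kinetic model
#'
#' Integrates \code{dc_int/dt = S_int (e * k(c))} (adaptive embedded
#' Runge-Kutta on log concentrations, followed by a damped Newton polish)
#' until \code{max |dc_i/dt| / c_i} falls below \code{tol}.  External
#' metabolites are clamped at the supplied concentrations.
#'
#' @param network an \code{\link{mb_network}}
#' @param constants an \code{mb_constants}
#' @param enzymes enzyme concentrations (mM), one per reaction
#' @param x_external log-concentrations (ln mM) of the external metabolites,
#'   named or in network order
#' @param x0_internal optional start values for internal log-concentrations
#' @param tol relative steady-state tolerance (1/s)
#' @param t_max integration horizon (s)
#' @return list(x, v, converged): full log-concentration vector, fluxes, and
#'   a convergence flag
#' @export
simulate_steady_state <- function(network, constants, enzymes, x_external,
                                  x0_internal = NULL, tol = 1e-9,
                                  t_max = 1e7) {
  S <- network$S
  int <- which(network$is_internal)
  ext <- which(!network$is_internal)
  if (length(enzymes) != ncol(S)) stopf("one enzyme level per reaction required")
  if (any(enzymes <= 0)) stopf("enzyme levels must be positive")
  if (length(x_external) != length(ext))
    stopf("x_external must match the number of external metabolites")
  x <- numeric(nrow(S))
  x[ext] <- x_external
  x[int] <- x0_internal %||% rep(log(0.1), length(int))
  rate <- make_rate_fn(constants, enzymes)
  S_int <- S[int, , drop = FALSE]
  dudt <- function(u) {
    x[int] <- u
    drop(S_int %*% rate(x)) / exp(u)   # d(log c)/dt
  }
  fluxres <- function(u) {
    x[int] <- u
    drop(S_int %*% rate(x))          # absolute net production (mM/s)
  }
  u <- x[int]
  diverged <- FALSE
  if (length(int) > 0) {
    # Newton first (tiny systems); fall back to short integration bursts to
    # globalise, then retry Newton.  Trajectories leaving any remotely
    # physiological window (|ln c| > 40, i.e. c beyond 1e-18..1e17 mM) have
    # no interior steady state and are abandoned early.
    best_resid <- Inf; stalls <- 0
    for (round in 1:6) {
      u <- newton_polish(dudt, u, tol)
      if (any(!is.finite(u)) || max(abs(u)) > 40) { diverged <- TRUE; break }
      resid <- max(abs(dudt(u)))
      if (resid < tol) break
      # give up on draws that stop making progress (no interior fixpoint or
      # pathologically slow mode); the caller retries with a fresh draw
      if (resid > best_resid * 0.3) stalls <- stalls + 1 else stalls <- 0
      best_resid <- min(best_resid, resid)
      if (stalls >= 2) break
      u <- rk_integrate(dudt, u, t_max / 6, tol, max_steps = 1200)
      if (any(!is.finite(u)) || max(abs(u)) > 40) { diverged <- TRUE; break }
    }
    if (diverged)
      return(list(x = replace(x, int, u), v = rep(NA_real_, ncol(S)),
                  converged = FALSE, residual = Inf))
    # final polish on the absolute flux residual so that |S_int v| is small
    # relative to the flux scale, not only relative to concentrations
    x[int] <- u
    vs <- max(abs(rate(x)), 1e-300)
    u <- newton_polish(fluxres, u, 1e-8 * vs)
  }
  x[int] <- u
  v <- rate(x)
  resid <- if (length(int)) max(abs(dudt(u))) else 0
  flux_ok <- length(int) == 0 ||
    max(abs(fluxres(u))) <= 1e-8 * max(max(abs(v)), 1e-12)
  list(x = x, v = v, converged = resid < tol && flux_ok, residual = resid)
}

# Vectorised CM-rate evaluator over all reactions: precomputes index
# structures once so repeated calls (ODE/Newton inner loops) are cheap.
make_rate_fn <- function(constants, enzymes) {
  p <- constants$pairs
  r <- length(constants$ln_Keq)
  sel <- split(seq_len(nrow(p)), p$reaction)
  met <- split(p$metabolite, p$reaction)
  sto <- split(p$stoich, p$reaction)
  function(xfull) {
    v <- numeric(r)
    for (l in seq_len(r)) {
      u <- xfull[met[[l]]] - constants$ln_KM[sel[[l]]]
      mlt <- abs(sto[[l]]); sub <- sto[[l]] < 0
      lnA <- sum(mlt[sub] * log1pexp(u[sub]))
      lnB <- sum(mlt[!sub] * log1pexp(u[!sub]))
      mx <- max(lnA, lnB)
      lnD <- mx + log(exp(lnA - mx) + exp(lnB - mx) - exp(-mx))
      v[l] <- exp(constants$ln_kcat_fwd[l] + sum(mlt[sub] * u[sub]) - lnD) -
        exp(constants$ln_kcat_bwd[l] + sum(mlt[!sub] * u[!sub]) - lnD)
    }
    v * enzymes
  }
}

# Embedded RK (Bogacki-Shampine 3(2)) with adaptive step on d(log c)/dt.
rk_integrate <- function(f, u, t_max, tol, rtol = 1e-6, max_steps = 20000) {
  t <- 0; h <- 1e-3
  k1 <- f(u)
  for (iter in seq_len(max_steps)) {
    if (max(abs(k1)) < tol || t >= t_max) break
    k2 <- f(u + h / 2 * k1)
    k3 <- f(u + 3 * h / 4 * k2)
    u_new <- u + h * (2 * k1 + 3 * k2 + 4 * k3) / 9
    k4 <- f(u_new)
    err <- max(abs(h * (-5 * k1 / 72 + k2 / 12 + k3 / 9 - k4 / 8)))
    sc <- rtol * (1 + max(abs(u)))
    if (!is.finite(err) || err > sc) {
      h <- h * max(0.2, 0.9 * (sc / max(err, 1e-300))^(1 / 3))
      next
    }
    t <- t + h; u <- u_new; k1 <- k4
    if (max(abs(u)) > 40) break     # runaway trajectory, no interior fixpoint
    h <- min(h * min(5, 0.9 * (sc / max(err, 1e-300))^(1 / 3)), t_max - t + 1)
  }
  u
}

# Damped Newton on f(u) = 0 with a numerical Jacobian (tiny systems).
newton_polish <- function(f, u, tol, max_iter = 60) {
  n <- length(u)
  for (it in seq_len(max_iter)) {
    fu <- f(u)
    if (max(abs(fu)) < tol / 10) break
    J <- matrix(0, n, n)
    hstep <- 1e-6 * pmax(1, abs(u))
    for (j in seq_len(n)) {
      up <- u; up[j] <- up[j] + hstep[j]
      J[, j] <- (f(up) - fu) / hstep[j]
    }
    step <- tryCatch(solve(J, -fu), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lam <- 1
    f0 <- max(abs(fu))
    repeat {
      un <- u + lam * step
      fn <- max(abs(f(un)))
      if ((is.finite(fn) && fn < f0) || lam < 1e-4) break
      lam <- lam / 2
    }
    if (!is.finite(fn) || fn >= f0) break
    u <- un
  }
  u
}

#' Apply multiplicative (lognormal) noise to positive values
#'
#' Each value is multiplied by \code{exp(N(0, log(gsd)))}; \code{gsd = 1}
#' is the identity.  Signs of (flux-like) negative inputs are preserved by
#' perturbing magnitudes.
#'
#' @param values numeric (nonzero) values
#' @param gsd geometric standard deviation (>= 1)
#' @param seed RNG seed
#' @return perturbed values
#' @export
add_noise <- function(values, gsd, seed = NULL) {
  if (gsd < 1) stopf("geometric standard deviation must be >= 1")
  if (gsd == 1) return(values)
  if (!is.null(seed)) set.seed(seed)
  values * exp(stats::rnorm(length(values), 0, log(gsd)))
}

#' Generate a full synthetic benchmark dataset
#'
#' Draws a ground-truth model from the priors, simulates \code{n_states}
#' steady states with random enzyme levels and external concentrations
#' (retrying draws until states converge, stay inside the default polytope
#' bounds, and keep all driving forces clear of the sign-constraint margin),
#' perturbs the observations with multiplicative noise, and assembles data
#' tables for the requested scenario:
#' \describe{
#'   \item{S1}{all kinetic constants (Keq, kcat+, kcat-, KM) as data}
#'   \item{S1K}{equilibrium constants only}
#'   \item{S2}{no kinetic data}
#' }
#' Fluxes are always provided (they are the known input of balancing).
#'
#' @param network an \code{\link{mb_network}}
#' @param scenario "S1", "S1K", or "S2"
#' @param n_states number of metabolic states (6 as in the benchmark runs)
#' @param state_gsd noise gsd for concentrations/enzymes/fluxes (1 = none)
#' @param kinetic_gsd noise gsd for kinetic constants (1 = none)
#' @param assumed_state_gsd,assumed_kinetic_gsd uncertainty written into the
#'   data tables (defaults: the noise gsd, floored at 1.05 for noise-free
#'   data so precisions stay finite)
#' @param priors a [prior_catalogue()]
#' @param bounds an [mb_bounds()] (truths are kept strictly inside)
#' @param seed RNG seed
#' @param max_retries model redraw budget
#' @return list(truth, data, fluxes, scenario): \code{truth} holds q_basic,
#'   constants, x/z/theta matrices and noise-free fluxes; \code{data} is the
#'   long-format table for [mb_problem()]; \code{fluxes} the (noisy) flux
#'   matrix to be used as the known input
#' @export
make_scenario_dataset <- function(network, scenario = c("S1", "S1K", "S2"),
                                  n_states = 6, state_gsd = 1,
                                  kinetic_gsd = 1,
                                  assumed_state_gsd = max(state_gsd, 1.05),
                                  assumed_kinetic_gsd = max(kinetic_gsd, 1.05),
                                  priors = prior_catalogue(),
                                  bounds = mb_bounds(), seed = 1,
                                  max_retries = 10) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  S <- network$S
  m <- nrow(S); r <- ncol(S)
  ext <- which(!network$is_internal)
  margin <- 2 * bounds$force_margin
  for (attempt in seq_len(max_retries)) {
    tm <- sample_true_model(network, priors,
                            seed = sample.int(2^31 - 1, 1))
    ok <- all(abs(tm$q_basic[tm$schema$idx_g]) < bounds$g_abs_max) &&
      all(tm$q_basic[tm$schema$idx_km] > log(bounds$km_min) &
            tm$q_basic[tm$schema$idx_km] < log(bounds$km_max)) &&
      all(tm$q_basic[tm$schema$idx_kv] > log(bounds$kv_min) &
            tm$q_basic[tm$schema$idx_kv] < log(bounds$kv_max))
    if (!ok) next
    X <- matrix(NA_real_, m, n_states)
    E <- matrix(NA_real_, r, n_states)
    V <- matrix(NA_real_, r, n_states)
    good <- TRUE
    for (s in seq_len(n_states)) {
      got <- FALSE
      for (try_s in seq_len(200)) {
        e <- exp(stats::rnorm(r, log(priors$enzyme$median),
                              log(priors$enzyme$gsd)))
        xe <- stats::rnorm(length(ext), log(priors$conc$median),
                           log(priors$conc$gsd))
        ss <- simulate_steady_state(network, tm$constants, e, xe)
        if (!ss$converged) next
        theta <- driving_forces(tm$constants$ln_Keq, S, ss$x)
        inside <- all(ss$x > log(bounds$conc_min) + 0.01) &&
          all(ss$x < log(bounds$conc_max) - 0.01) &&
          all(abs(theta) > margin | ss$v == 0) &&
          all(sign(ss$v) == sign(theta) | ss$v == 0) &&
          all(abs(ss$v) > 1e-12)
        if (!inside) next
        X[, s] <- ss$x; E[, s] <- e; V[, s] <- ss$v
        got <- TRUE; break
      }
      if (!got) { good <- FALSE; break }
    }
    if (good) {
      truth <- list(q_basic = tm$q_basic, constants = tm$constants,
                    x = X, e = E, v = V,
                    theta = driving_forces(tm$constants$ln_Keq, S, X))
      return(build_scenario_tables(network, truth, scenario, state_gsd,
                                   kinetic_gsd, assumed_state_gsd,
                                   assumed_kinetic_gsd))
    }
  }
  stopf("could not generate a valid synthetic dataset in %d attempts",
        max_retries)
}

build_scenario_tables <- function(network, truth, scenario, state_gsd,
                                  kinetic_gsd, assumed_state_gsd,
                                  assumed_kinetic_gsd) {
  m <- nrow(network$S); r <- ncol(network$S)
  n_states <- ncol(truth$x)
  rows <- list()
  add <- function(type, rxn, cpd, st, mean, gsd_assumed)
    rows[[length(rows) + 1]] <<- mb_data(type, rxn, cpd, st, mean, gsd_assumed)
  # state data: concentrations and enzymes, every metabolite/reaction/state
  conc <- add_noise(exp(as.vector(truth$x)), state_gsd)
  k <- 0
  for (s in seq_len(n_states)) for (i in seq_len(m)) {
    k <- k + 1
    add("concentration", NA, network$metabolite_ids[i], s, conc[k],
        assumed_state_gsd)
  }
  enz <- add_noise(as.vector(truth$e), state_gsd)
  k <- 0
  for (s in seq_len(n_states)) for (l in seq_len(r)) {
    k <- k + 1
    add("enzyme concentration", network$reaction_ids[l], NA, s, enz[k],
        assumed_state_gsd)
  }
  # kinetic data per scenario
  cst <- truth$constants
  if (scenario %in% c("S1", "S1K")) {
    keq <- add_noise(exp(cst$ln_Keq), kinetic_gsd)
    for (l in seq_len(r))
      add("equilibrium constant", network$reaction_ids[l], NA, NA, keq[l],
          assumed_kinetic_gsd)
  }
  if (scenario == "S1") {
    kcf <- add_noise(exp(cst$ln_kcat_fwd), kinetic_gsd)
    kcb <- add_noise(exp(cst$ln_kcat_bwd), kinetic_gsd)
    for (l in seq_len(r)) {
      add("catalytic rate constant (forward)", network$reaction_ids[l], NA,
          NA, kcf[l], assumed_kinetic_gsd)
      add("catalytic rate constant (backward)", network$reaction_ids[l], NA,
          NA, kcb[l], assumed_kinetic_gsd)
    }
    km <- add_noise(exp(cst$ln_KM), kinetic_gsd)
    for (k in seq_len(nrow(cst$pairs)))
      add("Michaelis constant",
          network$reaction_ids[cst$pairs$reaction[k]],
          network$metabolite_ids[cst$pairs$metabolite[k]], NA, km[k],
          assumed_kinetic_gsd)
  }
  fluxes <- truth$v
  if (state_gsd > 1)
    fluxes <- sign(truth$v) * add_noise(abs(truth$v), state_gsd)
  list(truth = truth, data = do.call(rbind, rows), fluxes = fluxes,
       scenario = scenario)
}
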