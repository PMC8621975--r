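# Problem assembly and posterior-mode optimisation.
#
# The optimisation vector is y = (q_basic, x per state).  The (q, x) part of
# the score is an exact quadratic assembled from priors on the basic
# variables plus kinetic/concentration data (each datum is a Gaussian on a
# linear function of y); the enzyme part is quad_alpha over z(y).  The
# solver is an interior log-barrier method (constrOptim with BFGS and
# analytic gradients); at alpha = 0 the problem is strictly convex, and
# alpha > 0 is solved by continuation from the alpha = 0 optimum.

QUANTITY_TYPES <- c("equilibrium constant", "catalytic rate constant (forward)",
                    "catalytic rate constant (backward)", "Michaelis constant",
                    "velocity constant", "concentration",
                    "enzyme concentration", "flux")

#' Solver options
#' @param grad_tol gradient-norm convergence tolerance (score units per log
#'   unit)
#' @param outer_eps barrier outer-loop tolerance
#' @param maxit inner BFGS iteration cap
#' @param n_starts multistart count used by convexity checks at alpha = 0
#' @param seed RNG seed for all stochastic elements
#' @return list of options
#' @export
mb_options <- function(grad_tol = 1e-6, outer_eps = 1e-9, maxit = 2000,
                       n_starts = 5, seed = 1) {
  list(grad_tol = grad_tol, outer_eps = outer_eps, maxit = maxit,
       n_starts = n_starts, seed = seed)
}

#' Assemble a model-balancing problem
#'
#' @param network an \code{\link{mb_network}}
#' @param fluxes matrix (reactions x states) of known, thermodynamically
#'   feasible fluxes (mM/s); every state is checked before solving
#' @param data optional long-format data table (see [mb_data()]), rows for
#'   kinetic constants, concentrations, and enzyme concentrations; values on
#'   linear scale with geometric standard deviations
#' @param priors a [prior_catalogue()]
#' @param bounds an [mb_bounds()]
#' @param alpha stringency parameter in [0, 1]; 0.5 by default
#' @param fixed optional named numeric vector pinning y coordinates (names
#'   as in the polytope layout, e.g. \code{"kV:R1"}, \code{"x:A:s1"})
#' @param options an [mb_options()]
#' @return an \code{mb_problem}
#' @export
mb_problem <- function(network, fluxes, data = NULL,
                       priors = prior_catalogue(), bounds = mb_bounds(),
                       alpha = 0.5, fixed = NULL, options = mb_options()) {
  schema <- build_schema(network)
  fluxes <- as.matrix(fluxes)
  polytope <- build_polytope(network, schema, fluxes, bounds)
  data <- validate_data(data, network)
  prepost <- build_preposterior(network, schema, polytope$layout, fluxes,
                                data, priors)
  fixed_idx <- integer(0); fixed_val <- numeric(0)
  if (!is.null(fixed)) {
    fixed_idx <- match(names(fixed), polytope$layout$names)
    if (anyNA(fixed_idx))
      stopf("unknown fixed coordinate(s): %s",
            paste(names(fixed)[is.na(fixed_idx)], collapse = ", "))
    fixed_val <- as.numeric(fixed)
  }
  structure(list(network = network, schema = schema, polytope = polytope,
                 fluxes = fluxes, data = data, priors = priors,
                 bounds = bounds, alpha = alpha, prepost = prepost,
                 fixed_idx = fixed_idx, fixed_val = fixed_val,
                 options = options),
            class = "mb_problem")
}

#' @export
print.mb_problem <- function(x, ...) {
  cat(sprintf(paste0("<mb_problem> %d reactions, %d metabolites, %d states, ",
                     "%d data rows, alpha = %g\n"),
              ncol(x$network$S), nrow(x$network$S),
              ncol(x$fluxes), NROW(x$data), x$alpha))
  invisible(x)
}

#' Construct a data table row set
#'
#' Long format mirroring the tab-delimited dialect: one row per measured
#' value, linear scale, with a geometric standard deviation (> 1) as the
#' assumed measurement uncertainty.
#'
#' @param QuantityType one of: equilibrium constant, catalytic rate constant
#'   (forward), catalytic rate constant (backward), Michaelis constant,
#'   velocity constant, concentration, enzyme concentration, flux
#' @param Reaction,Compound,State identifiers (NA where not applicable;
#'   State is the integer state index)
#' @param Mean linear-scale value
#' @param GeometricStd geometric standard deviation
#' @return a data.frame usable as the \code{data} argument of [mb_problem()]
#' @export
mb_data <- function(QuantityType, Reaction = NA, Compound = NA, State = NA,
                    Mean, GeometricStd) {
  data.frame(QuantityType = QuantityType, Reaction = Reaction,
             Compound = Compound, State = State, Mean = Mean,
             GeometricStd = GeometricStd, stringsAsFactors = FALSE)
}

validate_data <- function(data, network) {
  if (is.null(data) || nrow(data) == 0)
    return(mb_data(character(0), character(0), character(0), integer(0),
                   numeric(0), numeric(0)))
  bad <- setdiff(unique(data$QuantityType), QUANTITY_TYPES)
  if (length(bad)) stopf("unknown quantity type(s): %s", paste(bad, collapse = ", "))
  if (any(data$Mean <= 0)) stopf("data means must be positive (linear scale)")
  if (any(data$GeometricStd <= 1))
    stopf("geometric standard deviations must be > 1")
  need_rxn <- data$QuantityType %in% c("equilibrium constant",
                                       "catalytic rate constant (forward)",
                                       "catalytic rate constant (backward)",
                                       "Michaelis constant", "velocity constant",
                                       "enzyme concentration", "flux")
  if (any(is.na(data$Reaction[need_rxn])))
    stopf("missing reaction id in data rows")
  if (!all(data$Reaction[need_rxn] %in% network$reaction_ids))
    stopf("data rows reference unknown reactions")
  need_cpd <- data$QuantityType %in% c("Michaelis constant", "concentration")
  if (!all(data$Compound[need_cpd] %in% network$metabolite_ids))
    stopf("data rows reference unknown compounds")
  data
}

# Assemble the (q, x, z) preposterior blocks from priors and data.
build_preposterior <- function(network, schema, layout, fluxes, data, priors) {
  m <- nrow(network$S); r <- ncol(network$S)
  n_states <- layout$n_states
  # --- q block: prior on basic variables (diagonal) + linear-map data
  pm <- numeric(schema$n_basic); ps <- numeric(schema$n_basic)
  pm[schema$idx_g] <- 0;                 ps[schema$idx_g] <- priors$g$sd
  pm[schema$idx_km] <- log(priors$KM$median); ps[schema$idx_km] <- log(priors$KM$gsd)
  pm[schema$idx_kv] <- log(priors$kV$median); ps[schema$idx_kv] <- log(priors$kV$gsd)
  P <- diag(1 / ps^2, schema$n_basic)
  b <- pm / ps^2
  M <- schema$expansion_matrix; rw <- schema$rows
  kin <- data[data$QuantityType %in% c("equilibrium constant",
                                       "catalytic rate constant (forward)",
                                       "catalytic rate constant (backward)",
                                       "Michaelis constant",
                                       "velocity constant"), , drop = FALSE]
  if (nrow(kin) > 0) for (k in seq_len(nrow(kin))) {
    l <- match(kin$Reaction[k], network$reaction_ids)
    row <- switch(kin$QuantityType[k],
      "equilibrium constant" = rw$keq[l],
      "catalytic rate constant (forward)" = rw$kcat_fwd[l],
      "catalytic rate constant (backward)" = rw$kcat_bwd[l],
      "velocity constant" = rw$kv[l],
      "Michaelis constant" = {
        i <- match(kin$Compound[k], network$metabolite_ids)
        sel <- which(schema$pairs$reaction == l & schema$pairs$metabolite == i)
        if (length(sel) != 1)
          stopf("no Michaelis constant for (%s, %s): metabolite does not participate",
                kin$Reaction[k], kin$Compound[k])
        rw$km[sel]
      })
    a <- M[row, ]
    sd <- log(kin$GeometricStd[k])
    P <- P + tcrossprod(a) / sd^2
    b <- b + a * log(kin$Mean[k]) / sd^2
  }
  q_mean <- solve(P, b)
  # --- x block: diagonal per (metabolite, state)
  x_mean <- matrix(log(priors$conc$median), m, n_states)
  x_prec <- matrix(1 / log(priors$conc$gsd)^2, m, n_states)
  x_num <- x_mean * x_prec
  cdat <- data[data$QuantityType == "concentration", , drop = FALSE]
  if (nrow(cdat) > 0) for (k in seq_len(nrow(cdat))) {
    i <- match(cdat$Compound[k], network$metabolite_ids)
    s <- as.integer(cdat$State[k])
    sd <- log(cdat$GeometricStd[k])
    x_prec[i, s] <- x_prec[i, s] + 1 / sd^2
    x_num[i, s] <- x_num[i, s] + log(cdat$Mean[k]) / sd^2
  }
  x_mean <- x_num / x_prec
  # --- z block: diagonal per (reaction, state); zero-flux entries unused
  z_mean <- matrix(log(priors$enzyme$median), r, n_states)
  z_prec <- matrix(1 / log(priors$enzyme$gsd)^2, r, n_states)
  z_num <- z_mean * z_prec
  edat <- data[data$QuantityType == "enzyme concentration", , drop = FALSE]
  if (nrow(edat) > 0) for (k in seq_len(nrow(edat))) {
    l <- match(edat$Reaction[k], network$reaction_ids)
    s <- as.integer(edat$State[k])
    if (fluxes[l, s] == 0) next   # ignored for zero-flux reactions
    sd <- log(edat$GeometricStd[k])
    z_prec[l, s] <- z_prec[l, s] + 1 / sd^2
    z_num[l, s] <- z_num[l, s] + log(edat$Mean[k]) / sd^2
  }
  z_mean <- z_num / z_prec
  list(q_prec = P, q_mean = q_mean,
       x_mean = x_mean, x_sd = sqrt(1 / x_prec),
       z_mean = z_mean, z_sd = sqrt(1 / z_prec))
}

# Reduced inequality system over the free coordinates.
reduced_constraints <- function(problem) {
  poly <- problem$polytope
  n <- poly$layout$n_y
  free <- setdiff(seq_len(n), problem$fixed_idx)
  ui <- poly$ui[, free, drop = FALSE]
  ci <- poly$ci
  if (length(problem$fixed_idx))
    ci <- ci - drop(poly$ui[, problem$fixed_idx, drop = FALSE] %*%
                      problem$fixed_val)
  nz <- rowSums(abs(ui)) > 1e-12
  if (any(ci[!nz] > 1e-9))
    stopf("fixed coordinates violate the polytope")
  list(ui = ui[nz, , drop = FALSE], ci = ci[nz], free = free)
}

embed_y <- function(problem, y_free, free) {
  y <- numeric(problem$polytope$layout$n_y)
  y[free] <- y_free
  if (length(problem$fixed_idx)) y[problem$fixed_idx] <- problem$fixed_val
  y
}

#' Find a strictly interior starting point
#'
#' Uses the preposterior means for (q, x) when they are strictly feasible;
#' otherwise projects them onto a slightly shrunken polytope by a
#' least-squares feasibility program, falling back to the maximal-slack
#' (Chebyshev-style) centre.
#'
#' @param problem an [mb_problem()]
#' @param margin strict-feasibility margin required of the start
#' @return a full y vector strictly inside the polytope
#' @export
initialize_balancing <- function(problem, margin = 1e-6) {
  rc <- reduced_constraints(problem)
  lay <- problem$polytope$layout
  target <- numeric(lay$n_y)
  target[lay$idx_q] <- problem$prepost$q_mean
  for (s in seq_len(lay$n_states))
    target[lay$idx_x[[s]]] <- problem$prepost$x_mean[, s]
  t_free <- target[rc$free]
  norms <- sqrt(rowSums(rc$ui^2))
  if (min(drop(rc$ui %*% t_free) - rc$ci - margin * norms) > 0)
    return(embed_y(problem, t_free, rc$free))
  cc <- chebyshev_centre(rc$ui, rc$ci, problem$polytope$lower[rc$free],
                         problem$polytope$upper[rc$free])
  if (!cc$feasible || cc$slack <= margin)
    stopf("feasible polytope is empty (or thinner than the margin)")
  delta <- min(margin, cc$slack / 2)
  proj <- tryCatch(
    stats::constrOptim(cc$y,
                       f = function(w) sum((w - t_free)^2) / 2,
                       grad = function(w) w - t_free,
                       ui = rc$ui, ci = rc$ci + delta * norms,
                       method = "BFGS", outer.eps = 1e-10,
                       outer.iterations = 60,
                       control = list(maxit = 500, reltol = 1e-13)),
    error = function(e) NULL)
  y_free <- if (is.null(proj)) cc$y else proj$par
  embed_y(problem, y_free, rc$free)
}

# One barrier solve at a given alpha from a strictly feasible start.
# Same adaptive log-barrier scheme as stats::constrOptim (Lange's method,
# which converges at fixed mu), but hardened for optima on the boundary:
# when an inner solve drives a margin to exactly zero, the loop stops
# cleanly at the last valid iterate instead of propagating NaN.
solve_at_alpha <- function(problem, y0_free, rc, alpha) {
  # optim asks for value and gradient at the same point; compute once
  cache <- new.env(parent = emptyenv())
  score_at <- function(w) {
    if (!is.null(cache$w) && identical(w, cache$w)) return(cache$sc)
    sc <- assemble_posterior_score(problem, embed_y(problem, w, rc$free),
                                   alpha)
    cache$w <- w; cache$sc <- sc
    sc
  }
  fn <- function(w) score_at(w)$total
  gr <- function(w) score_at(w)$gradient[rc$free]
  ui <- rc$ui; ci <- rc$ci; mu <- 1e-4
  theta <- y0_free
  marg0 <- min(drop(ui %*% theta) - ci)
  if (marg0 <= 0)
    stopf("starting point is not strictly interior (margin %.3g)", marg0)
  f_old <- fn(theta)
  convergence <- 1
  for (outer in seq_len(100)) {
    theta_old <- theta
    gio <- drop(ui %*% theta_old) - ci
    Rf <- function(th) {
      gi <- drop(ui %*% th) - ci
      if (any(gi <= 0)) return(NaN)
      bar <- sum(gio * log(gi) - drop(ui %*% th))
      if (!is.finite(bar)) return(NaN)
      fn(th) - mu * bar
    }
    dRf <- function(th) {
      gi <- drop(ui %*% th) - ci
      gr(th) - mu * colSums(ui * gio / gi - ui)
    }
    a <- tryCatch(stats::optim(theta_old, Rf, dRf, method = "BFGS",
                               control = list(maxit = problem$options$maxit,
                                              reltol = 1e-12)),
                  error = function(e) NULL)
    if (is.null(a)) { convergence <- 0; break }   # boundary contact
    cand <- a$par
    gi_cand <- drop(ui %*% cand) - ci
    if (any(gi_cand < 0)) {
      # pull back onto the segment towards the last interior iterate
      viol <- gi_cand < 0
      t <- max((-gi_cand[viol] + 1e-14) /
                 (gio[viol] - gi_cand[viol] + 1e-300))
      t <- min(max(t, 0), 1)
      cand <- cand + t * (theta_old - cand)
    }
    f_new <- fn(cand)
    if (!is.finite(f_new)) { convergence <- 0; break }
    theta <- cand
    if (abs(f_new - f_old) <
        (1e-3 + abs(f_new)) * problem$options$outer_eps) {
      f_old <- f_new; convergence <- 0; break
    }
    f_old <- f_new
  }
  list(par = theta, value = f_old, convergence = convergence)
}

random_interior_point <- function(rc, centre_free, lower, upper, rng_scale = 1) {
  d <- stats::rnorm(length(centre_free))
  d <- d / sqrt(sum(d^2))
  margins <- drop(rc$ui %*% centre_free) - rc$ci
  dd <- drop(rc$ui %*% d)
  lim <- margins[dd < 0] / (-dd[dd < 0])
  tmax <- if (length(lim)) min(lim) else max(upper - lower)
  y <- centre_free + stats::runif(1, 0.05, 0.8) * tmax * d * rng_scale
  # numerical safety: fall back towards the centre if the step grazed the
  # boundary
  if (min(drop(rc$ui %*% y) - rc$ci) <= 1e-9) y <- (y + centre_free) / 2
  if (min(drop(rc$ui %*% y) - rc$ci) <= 1e-9) y <- centre_free
  y
}

#' Solve the model-balancing problem
#'
#' Minimises the posterior loss R(y) over the feasible polytope.  For
#' \code{alpha > 0} the default is a continuation: first solve the strictly
#' convex \code{alpha = 0} problem, then warm-start the target alpha from
#' its optimum.  With \code{multistart = TRUE}, additional random interior
#' starts are run and coordinate-wise agreement is recorded (a convexity
#' diagnostic; at alpha = 0 all starts must agree).
#'
#' @param problem an [mb_problem()]
#' @param multistart run \code{options$n_starts} random restarts
#' @return an \code{mb_result}: optimal basic vector and expanded constants,
#'   per-state log-concentrations \code{x}, log-enzyme levels \code{z}
#'   (\code{NA} for zero-flux reactions), forces \code{theta}, the score
#'   breakdown, and convergence diagnostics
#' @export
balance <- function(problem, multistart = FALSE) {
  rc <- reduced_constraints(problem)
  y0 <- initialize_balancing(problem)
  y0_free <- y0[rc$free]
  runs <- list()
  run_from <- function(start_free) {
    o0 <- solve_at_alpha(problem, start_free, rc, 0)
    if (problem$alpha > 0)
      o0 <- solve_at_alpha(problem, o0$par, rc, problem$alpha)
    o0
  }
  runs[[1]] <- run_from(y0_free)
  if (multistart) {
    set.seed(problem$options$seed)
    cc <- chebyshev_centre(rc$ui, rc$ci, problem$polytope$lower[rc$free],
                           problem$polytope$upper[rc$free])
    for (k in seq_len(problem$options$n_starts - 1)) {
      run <- NULL
      for (try_k in 1:3) {
        st <- random_interior_point(rc, cc$y,
                                    problem$polytope$lower[rc$free],
                                    problem$polytope$upper[rc$free])
        run <- tryCatch(run_from(st), error = function(e) NULL)
        if (!is.null(run)) break
      }
      if (is.null(run)) stopf("multistart run %d failed to solve", k + 1)
      runs[[k + 1]] <- run
    }
  }
  vals <- vapply(runs, function(o) o$value, 0)
  best <- runs[[which.min(vals)]]
  spread <- if (length(runs) > 1)
    max(vapply(runs, function(o) max(abs(o$par - best$par)), 0)) else 0
  y_star <- embed_y(problem, best$par, rc$free)
  finalize_result(problem, y_star, best, spread, length(runs))
}

finalize_result <- function(problem, y_star, opt, multistart_spread, n_runs) {
  lay <- problem$polytope$layout
  sc <- assemble_posterior_score(problem, y_star)
  constants <- expand_constants(problem$schema, y_star[lay$idx_q])
  m <- lay$m; r <- ncol(problem$network$S)
  X <- sapply(seq_len(lay$n_states), function(s) y_star[lay$idx_x[[s]]])
  X <- matrix(X, m, lay$n_states,
              dimnames = list(problem$network$metabolite_ids,
                              paste0("s", seq_len(lay$n_states))))
  theta <- driving_forces(constants$ln_Keq, problem$network$S, X)
  theta <- matrix(theta, r, lay$n_states,
                  dimnames = list(problem$network$reaction_ids,
                                  colnames(X)))
  Z <- matrix(NA_real_, r, lay$n_states,
              dimnames = dimnames(theta))
  for (s in seq_len(lay$n_states))
    Z[sc$z[[s]]$active, s] <- sc$z[[s]]$z
  grad_free <- sc$gradient[setdiff(seq_len(lay$n_y), problem$fixed_idx)]
  kkt <- kkt_residual(problem, y_star, sc$gradient)
  structure(list(
    y_star = y_star, constants = constants, x = X, z = Z, theta = theta,
    score = sc$parts, total = sc$total, alpha = problem$alpha,
    diagnostics = list(converged = opt$convergence == 0,
                       solver_value = opt$value,
                       grad_norm = sqrt(sum(grad_free^2)),
                       kkt_residual = kkt,
                       polytope_margin = polytope_margin(problem$polytope,
                                                         y_star),
                       multistart_spread = multistart_spread,
                       multistart_agree = multistart_spread < 1e-4,
                       n_runs = n_runs),
    problem = problem
  ), class = "mb_result")
}

# Stationarity residual ||grad - A' lambda|| with lambda >= 0 supported on
# near-active constraints, by a few nonnegative coordinate-descent sweeps.
kkt_residual <- function(problem, y, grad) {
  free <- setdiff(seq_len(problem$polytope$layout$n_y), problem$fixed_idx)
  ui <- problem$polytope$ui[, free, drop = FALSE]
  margins <- drop(problem$polytope$ui %*% y) - problem$polytope$ci
  act <- which(margins < 1e-5 * (1 + abs(problem$polytope$ci)))
  g <- grad[free]
  if (length(act) == 0) return(sqrt(sum(g^2)))
  A <- ui[act, , drop = FALSE]
  lam <- numeric(length(act))
  resid <- g
  for (sweep in 1:25) for (i in seq_along(lam)) {
    ai <- A[i, ]
    step <- sum(ai * resid) / sum(ai * ai)
    new <- max(0, lam[i] + step)
    resid <- resid - (new - lam[i]) * ai
    lam[i] <- new
  }
  sqrt(sum(resid^2))
}

#' @export
print.mb_result <- function(x, ...) {
  cat(sprintf("<mb_result> alpha = %g, total score %.4f\n", x$alpha, x$total))
  cat(sprintf("  converged: %s | grad norm %.2e | KKT residual %.2e\n",
              x$diagnostics$converged, x$diagnostics$grad_norm,
              x$diagnostics$kkt_residual))
  invisible(x)
}

#' Maximum-likelihood mode
#'
#' Re-solves the problem with prior standard deviations inflated by a large
#' factor (flat priors), preserving all bounds; data then dominate wherever
#' they exist, and data-free quantities become bound/polytope-driven.
#'
#' @param problem an [mb_problem()]
#' @param inflate multiplicative factor on all prior (log-scale) sds
#' @param ... passed to [balance()]
#' @return an \code{mb_result}; \code{diagnostics$prior_insensitive} flags a
#'   run without any data rows
#' @export
maximum_likelihood_mode <- function(problem, inflate = 1e3, ...) {
  pr <- problem$priors
  for (nm in c("g", "Keq", "kV", "KM", "conc", "enzyme")) {
    # cap the flat-prior log-sd at 30 natural-log units to stay finite
    if (!is.null(pr[[nm]]$gsd))
      pr[[nm]]$gsd <- exp(pmin(log(pr[[nm]]$gsd) * inflate, 30))
    if (!is.null(pr[[nm]]$sd)) pr[[nm]]$sd <- pmin(pr[[nm]]$sd * inflate, 30)
  }
  p2 <- mb_problem(problem$network, problem$fluxes, problem$data, pr,
                   problem$bounds, problem$alpha,
                   fixed = if (length(problem$fixed_idx))
                     stats::setNames(problem$fixed_val,
                       problem$polytope$layout$names[problem$fixed_idx]),
                   options = problem$options)
  res <- balance(p2, ...)
  res$diagnostics$prior_insensitive <- nrow(problem$data) == 0
  res
}
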