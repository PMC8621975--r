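# Thermodynamic forces, flux-sign feasibility, and the convex feasible
# polytope over y = (basic kinetic vector, log-concentrations per state).
# All constraints are linear in y; strict force-sign inequalities are
# represented with a small margin so that eta_rev stays bounded away from 0.

#' Bounds and margin configuration
#'
#' @param conc_min,conc_max metabolite concentration bounds in mM
#' @param g_abs_max bound on |g| (dimensionless, units of RT)
#' @param km_min,km_max Michaelis constant bounds in mM
#' @param kv_min,kv_max velocity constant bounds in 1/s
#' @param force_margin margin epsilon (RT units) for active-reaction
#'   force-sign constraints; keeps enzyme demand finite
#' @param conc_overrides optional named list of \code{c(min, max)} per
#'   metabolite id, overriding the global concentration bounds
#' @return an \code{mb_bounds} list
#' @export
mb_bounds <- function(conc_min = 1e-6, conc_max = 1e2, g_abs_max = 50,
                      km_min = 1e-5, km_max = 1e3,
                      kv_min = 1e-4, kv_max = 1e5,
                      force_margin = 1e-3, conc_overrides = list()) {
  b <- list(conc_min = conc_min, conc_max = conc_max, g_abs_max = g_abs_max,
            km_min = km_min, km_max = km_max, kv_min = kv_min,
            kv_max = kv_max, force_margin = force_margin,
            conc_overrides = conc_overrides)
  for (ov in conc_overrides)
    if (ov[1] > ov[2]) stopf("conc override with min > max")
  if (conc_min > conc_max) stopf("conc_min > conc_max")
  structure(b, class = "mb_bounds")
}

#' Read a key-value bounds configuration file
#'
#' Lines of the form \code{key<TAB>value}; recognised keys are the arguments
#' of [mb_bounds()] plus metabolite-specific \code{conc_min:<id>} /
#' \code{conc_max:<id>} overrides.
#' @param path file path
#' @return an \code{mb_bounds}
#' @export
read_bounds <- function(path) {
  kv <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  args <- list(); ov <- list()
  for (i in seq_len(nrow(kv))) {
    key <- kv[i, 1]; val <- as.numeric(kv[i, 2])
    if (grepl("^conc_(min|max):", key)) {
      id <- sub("^conc_(min|max):", "", key)
      cur <- ov[[id]] %||% c(NA, NA)
      if (grepl("^conc_min:", key)) cur[1] <- val else cur[2] <- val
      ov[[id]] <- cur
    } else args[[key]] <- val
  }
  b <- do.call(mb_bounds, args)
  if (length(ov)) {
    for (id in names(ov)) {
      cur <- ov[[id]]
      if (is.na(cur[1])) cur[1] <- b$conc_min
      if (is.na(cur[2])) cur[2] <- b$conc_max
      ov[[id]] <- cur
    }
    b$conc_overrides <- ov
  }
  b
}

#' Thermodynamic driving forces
#'
#' \code{theta = ln_Keq - t(S) \%*\% x}, in units of RT.  The sign of theta
#' dictates the feasible flux direction of each reaction.
#'
#' @param ln_Keq log equilibrium constants, one per reaction
#' @param S stoichiometric matrix (metabolites x reactions)
#' @param x log-concentration vector (or matrix, metabolites x states)
#' @return vector (or matrix, reactions x states) of forces
#' @export
driving_forces <- function(ln_Keq, S, x) {
  if (length(ln_Keq) != ncol(S)) stopf("ln_Keq length != number of reactions")
  if (NROW(x) != nrow(S)) stopf("x length != number of metabolites")
  out <- drop(unname(ln_Keq) - crossprod(S, x))
  if (is.matrix(out)) dimnames(out) <- NULL else names(out) <- NULL
  out
}

# Wrapper around boot::simplex: maximise obj'w s.t. A w <= b, w >= 0,
# splitting rows by rhs sign as boot::simplex expects non-negative rhs.
lp_boot <- function(obj, A, b) {
  pos <- b >= 0
  res <- boot::simplex(a = obj,
                       A1 = if (any(pos)) A[pos, , drop = FALSE],
                       b1 = if (any(pos)) b[pos],
                       A2 = if (any(!pos)) -A[!pos, , drop = FALSE],
                       b2 = if (any(!pos)) -b[!pos],
                       maxi = TRUE, n.iter = 50 * (nrow(A) + ncol(A)))
  res
}

# Maximal-slack (Chebyshev-style) interior point of {y : ui y >= ci,
# lower <= y <= upper}.  Returns list(y, slack, feasible); slack is the
# minimal row-normalised margin at the returned point.
chebyshev_centre <- function(ui, ci, lower, upper) {
  n <- ncol(ui)
  norms <- sqrt(rowSums(ui^2))
  # variables w = (y - lower, t); constraints in <= form:
  #   -ui (w + lower) + t * norms <= -ci      (sign constraints / general)
  #    w_j <= upper_j - lower_j               (box top; t capped at big)
  width <- upper - lower
  tcap <- max(width) / 2 + 1
  A <- rbind(cbind(-ui, norms),
             cbind(diag(n), rep(0, n)),
             c(rep(0, n), 1))
  b <- c(drop(ui %*% lower) - ci, width, tcap)
  obj <- c(rep(0, n), 1)
  res <- lp_boot(obj, A, b)
  if (res$solved < 0)
    return(list(y = NULL, slack = -Inf, feasible = FALSE))
  w <- res$soln[seq_len(n)]
  y <- w + lower
  slack <- min((drop(ui %*% y) - ci) / norms)
  list(y = y, slack = slack, feasible = slack > 0)
}

#' Check thermodynamic feasibility of a flux vector
#'
#' Solves a linear feasibility problem for (g, x): active reactions must
#' admit \code{sign(v_l) * theta_l >= force_margin} with ln Keq = -t(S) g
#' and concentrations within bounds.  Zero flux vectors are always feasible.
#'
#' @param network an \code{\link{mb_network}}
#' @param v flux vector, one entry per reaction
#' @param bounds an [mb_bounds()]
#' @return list with \code{feasible} (logical), \code{slack} (minimal
#'   normalised margin beyond the sign constraint), and when feasible a
#'   witness \code{g} and \code{x} (log mM)
#' @export
check_flux_feasibility <- function(network, v, bounds = mb_bounds()) {
  S <- network$S
  m <- nrow(S); r <- ncol(S)
  if (length(v) != r) stopf("flux vector length != number of reactions")
  active <- which(v != 0)
  lower <- c(rep(-bounds$g_abs_max, m), x_lower(network, bounds))
  upper <- c(rep(bounds$g_abs_max, m), x_upper(network, bounds))
  if (length(active) == 0) {
    y <- (lower + upper) / 2
    return(list(feasible = TRUE, slack = Inf,
                g = y[seq_len(m)], x = y[m + seq_len(m)]))
  }
  # theta_l = -sum_i S_il (g_i + x_i)
  ui <- t(sapply(active, function(l) {
    a <- numeric(2 * m)
    a[seq_len(m)] <- -sign(v[l]) * S[, l]
    a[m + seq_len(m)] <- -sign(v[l]) * S[, l]
    a
  }))
  ci <- rep(bounds$force_margin, length(active))
  cc <- chebyshev_centre(ui, ci, lower, upper)
  if (!cc$feasible) return(list(feasible = FALSE, slack = cc$slack))
  list(feasible = TRUE, slack = cc$slack,
       g = cc$y[seq_len(m)], x = cc$y[m + seq_len(m)])
}

x_lower <- function(network, bounds) {
  lo <- rep(log(bounds$conc_min), nrow(network$S))
  for (id in names(bounds$conc_overrides))
    lo[match(id, network$metabolite_ids)] <- log(bounds$conc_overrides[[id]][1])
  lo
}
x_upper <- function(network, bounds) {
  up <- rep(log(bounds$conc_max), nrow(network$S))
  for (id in names(bounds$conc_overrides))
    up[match(id, network$metabolite_ids)] <- log(bounds$conc_overrides[[id]][2])
  up
}

# Layout of the full optimisation vector y = (q_basic, x per state).
y_layout <- function(schema, n_states) {
  m <- nrow(schema$network$S)
  nb <- schema$n_basic
  idx_x <- lapply(seq_len(n_states), function(s) nb + (s - 1) * m + seq_len(m))
  names_y <- c(schema$basic_names,
               unlist(lapply(seq_len(n_states), function(s)
                 paste0("x:", schema$network$metabolite_ids, ":s", s))))
  list(n_y = nb + m * n_states, n_states = n_states, m = m,
       idx_q = seq_len(nb), idx_x = idx_x, names = names_y)
}

#' Build the feasible polytope over (basic vector, per-state log profiles)
#'
#' Assembles the linear inequality system \code{ui \%*\% y >= ci} containing
#' the box bounds on g, ln KM, ln kV and per-state log-concentrations, and
#' the force-sign constraints \code{sign(v_l) * theta_l >= force_margin} for
#' every active reaction in every state.  Zero-flux reactions contribute no
#' sign constraint.
#'
#' @param network an \code{\link{mb_network}}
#' @param schema the matching \code{mb_schema}
#' @param fluxes matrix (reactions x states) of known fluxes
#' @param bounds an [mb_bounds()]
#' @return an \code{mb_polytope}: list(ui, ci, layout, lower, upper, bounds)
#' @export
build_polytope <- function(network, schema, fluxes, bounds = mb_bounds()) {
  fluxes <- as.matrix(fluxes)
  if (nrow(fluxes) != ncol(network$S))
    stopf("fluxes must have one row per reaction")
  n_states <- ncol(fluxes)
  for (s in seq_len(n_states)) {
    fz <- check_flux_feasibility(network, fluxes[, s], bounds)
    if (!fz$feasible)
      stopf("fluxes of state %d are thermodynamically infeasible (slack %.3g)",
            s, fz$slack)
  }
  lay <- y_layout(schema, n_states)
  S <- network$S
  m <- lay$m
  lower <- numeric(lay$n_y); upper <- numeric(lay$n_y)
  lower[schema$idx_g] <- -bounds$g_abs_max
  upper[schema$idx_g] <- bounds$g_abs_max
  lower[schema$idx_km] <- log(bounds$km_min)
  upper[schema$idx_km] <- log(bounds$km_max)
  lower[schema$idx_kv] <- log(bounds$kv_min)
  upper[schema$idx_kv] <- log(bounds$kv_max)
  xl <- x_lower(network, bounds); xu <- x_upper(network, bounds)
  for (s in seq_len(n_states)) {
    lower[lay$idx_x[[s]]] <- xl
    upper[lay$idx_x[[s]]] <- xu
  }
  if (any(lower >= upper)) stopf("degenerate bounds: lower >= upper")
  rows <- list(); cis <- c(); labels <- c()
  for (s in seq_len(n_states)) {
    for (l in which(fluxes[, s] != 0)) {
      a <- numeric(lay$n_y)
      sg <- sign(fluxes[l, s])
      a[schema$idx_g] <- -sg * S[, l]
      a[lay$idx_x[[s]]] <- -sg * S[, l]
      rows[[length(rows) + 1]] <- a
      cis <- c(cis, bounds$force_margin)
      labels <- c(labels, sprintf("force:%s:s%d", network$reaction_ids[l], s))
    }
  }
  # box bounds as explicit rows so a single (ui, ci) system describes the set
  I <- diag(lay$n_y)
  ui <- rbind(do.call(rbind, rows), I, -I)
  ci <- c(cis, lower, -upper)
  labels <- c(labels, paste0("lb:", lay$names), paste0("ub:", lay$names))
  rownames(ui) <- labels
  structure(list(ui = ui, ci = ci, layout = lay, lower = lower,
                 upper = upper, bounds = bounds, fluxes = fluxes),
            class = "mb_polytope")
}

#' @export
print.mb_polytope <- function(x, ...) {
  cat(sprintf("<mb_polytope> %d variables, %d inequality rows\n",
              x$layout$n_y, nrow(x$ui)))
  invisible(x)
}

#' Minimal constraint margin of a point (negative = outside)
#' @param polytope an \code{mb_polytope}
#' @param y candidate point
#' @return minimal value of \code{ui y - ci}
#' @export
polytope_margin <- function(polytope, y) {
  min(drop(polytope$ui %*% y) - polytope$ci)
}

# Maximal-slack interior point of a built polytope
polytope_centre <- function(polytope) {
  cc <- chebyshev_centre(polytope$ui, polytope$ci,
                         polytope$lower, polytope$upper)
  if (!cc$feasible) stopf("polytope is empty")
  cc$y
}
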