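# Modular reversible rate laws (common modular / CM form), efficiency
# factorisation k = kcat+ * eta_rev * eta_sat, and the log enzyme-demand
# function z(y) = ln v - ln k with its analytic gradient in the space of
# log kinetic constants and log concentrations.  Evaluation is done on log
# scale throughout so polytope corners do not overflow.

#' Reversibility efficiency
#'
#' \code{eta_rev = 1 - exp(-theta)}: the fraction of the forward capacity
#' that survives backward flux at driving force theta (RT units).
#' @param theta driving force(s)
#' @return efficiency in (0,1) for theta > 0; 0 at equilibrium
#' @export
eta_rev <- function(theta) -expm1(-theta)

# Log-scale pieces of the CM denominator for one reaction.
# x, kappa: log concentration / log KM for the reaction's reactants.
# Returns lnA (substrate side), lnB (product side), lnD with
# D = A + B - 1 >= 1, plus per-reactant occupancies for gradients.
cm_denominator <- function(x, kappa, stoich) {
  u <- x - kappa                       # ln(c/KM)
  mlt <- abs(stoich)
  sub <- stoich < 0
  lnA <- sum(mlt[sub] * log1pexp(u[sub]))
  lnB <- sum(mlt[!sub] * log1pexp(u[!sub]))
  mx <- max(lnA, lnB)
  lnD <- mx + log(exp(lnA - mx) + exp(lnB - mx) - exp(-mx))
  occ <- stats::plogis(u)              # r/(1+r) per reactant
  list(lnA = lnA, lnB = lnB, lnD = lnD, u = u, occ = occ, mlt = mlt,
       sub = sub)
}

#' Catalytic rate of one reaction under the common modular (CM) rate law
#'
#' \code{k = (kcat+ prod_sub (c/KM)^m - kcat- prod_prod (c/KM)^m) / D} with
#' \code{D = prod_sub (1+c/KM)^m + prod_prod (1+c/KM)^m - 1}; for a uni-uni
#' reaction this is the reversible Michaelis-Menten rate per unit enzyme.
#'
#' @param constants an \code{mb_constants} (see [expand_constants()])
#' @param x log-concentration vector over all metabolites (ln mM)
#' @param l reaction index
#' @return catalytic rate k in 1/s (sign = sign of the driving force)
#' @export
catalytic_rate_cm <- function(constants, x, l) {
  p <- constants$pairs
  sel <- which(p$reaction == l)
  if (length(sel) == 0) stopf("reaction %s has no reactants", l)
  idx <- p$metabolite[sel]
  den <- cm_denominator(x[idx], constants$ln_KM[sel], p$stoich[sel])
  fwd <- exp(constants$ln_kcat_fwd[[l]] +
               sum(den$mlt[den$sub] * den$u[den$sub]) - den$lnD)
  bwd <- exp(constants$ln_kcat_bwd[[l]] +
               sum(den$mlt[!den$sub] * den$u[!den$sub]) - den$lnD)
  unname(fwd - bwd)
}

#' Saturation efficiency of one reaction (CM rate law)
#'
#' Occupancy of the flux-carrying side over the CM denominator; in (0,1].
#' With the direction taken from the sign of the driving force, the
#' factorisation \code{k = kcat(direction) * eta_rev(|theta|) * eta_sat}
#' holds exactly for Haldane-consistent constants.
#'
#' @inheritParams catalytic_rate_cm
#' @param direction +1 (forward) or -1 (backward); defaults to forward
#' @return efficiency in (0, 1]
#' @export
eta_sat <- function(constants, x, l, direction = 1) {
  p <- constants$pairs
  sel <- which(p$reaction == l)
  idx <- p$metabolite[sel]
  den <- cm_denominator(x[idx], constants$ln_KM[sel], p$stoich[sel])
  side <- if (direction > 0) den$sub else !den$sub
  exp(sum(den$mlt[side] * den$u[side]) - den$lnD)
}

#' Enzyme demand of one reaction
#'
#' The enzyme concentration needed to carry flux \code{v} at catalytic rate
#' \code{k}: \code{e = v / k}, equivalently flux times the reaction time
#' \code{tau = 1/k}.
#' @param v flux (mM/s), nonzero
#' @param k catalytic rate (1/s), same sign as \code{v}
#' @return enzyme demand in mM (positive)
#' @export
enzyme_demand <- function(v, k) {
  if (any(v == 0))
    stopf("enzyme demand is undefined at zero flux; omit the term upstream")
  if (any(k == 0) || any(sign(v) != sign(k)))
    stopf("thermodynamic inconsistency: flux and catalytic rate disagree in sign")
  v / k
}

#' Log enzyme demands and their Jacobian with respect to y
#'
#' For every active reaction of state \code{s}, computes
#' \code{z_l = ln v_l - ln k_l(y)} where \code{y = (q_basic, x per state)},
#' together with the analytic Jacobian \code{d z / d y}.  Both are convex in
#' y; the Jacobian rows touch only the basic block and the state's x block.
#'
#' @param schema an \code{mb_schema}
#' @param y full optimisation vector (see [build_polytope()] layout)
#' @param fluxes flux matrix (reactions x states)
#' @param s state index
#' @param layout the y layout (from a polytope); inferred when \code{NULL}
#' @return list(z, J, active, theta): z and theta for active reactions of
#'   the state, J the (n_active x length(y)) Jacobian
#' @export
log_enzyme_demand_and_gradient <- function(schema, y, fluxes, s,
                                           layout = NULL) {
  fluxes <- as.matrix(fluxes)
  if (is.null(layout)) layout <- y_layout(schema, ncol(fluxes))
  S <- schema$network$S
  p <- schema$pairs
  g <- y[schema$idx_g]
  kap_all <- y[schema$idx_km]
  kv <- y[schema$idx_kv]
  xs <- y[layout$idx_x[[s]]]
  ln_keq <- drop(-crossprod(S, g))
  theta <- drop(ln_keq - crossprod(S, xs))
  active <- which(fluxes[, s] != 0)
  z <- numeric(length(active))
  J <- matrix(0, length(active), layout$n_y)
  for (a in seq_along(active)) {
    l <- active[a]
    sg <- sign(fluxes[l, s])
    t_ <- sg * theta[l]
    if (t_ <= 0)
      stopf("state %d, reaction %s: force sign conflicts with flux (outside polytope)",
            s, schema$network$reaction_ids[l])
    sel <- which(p$reaction == l)
    idx <- p$metabolite[sel]
    den <- cm_denominator(xs[idx], kap_all[sel], p$stoich[sel])
    h <- ln_keq[l] - sum(p$stoich[sel] * kap_all[sel])
    ln_kcat_dir <- kv[l] + sg * h / 2
    side <- if (sg > 0) den$sub else !den$sub
    z[a] <- log(abs(fluxes[l, s])) - ln_kcat_dir - log1mexp(t_) -
      sum(den$mlt[side] * den$u[side]) + den$lnD
    # gradient pieces
    dz_dtheta <- -sg / expm1(t_)          # from -log(1 - exp(-sg*theta))
    # rho_i = d lnD / d x_i (equal to -d lnD / d kappa_i)
    wA <- exp(den$lnA - den$lnD); wB <- exp(den$lnB - den$lnD)
    rho <- ifelse(den$sub, wA, wB) * den$mlt * den$occ
    # g block: via ln_keq in both kcat(direction) and theta
    J[a, schema$idx_g] <- S[, l] * (sg / 2) - S[, l] * dz_dtheta
    # kV block
    J[a, schema$idx_kv[l]] <- -1
    # KM block
    J[a, schema$idx_km[sel]] <- (sg / 2) * p$stoich[sel] +
      ifelse(side, den$mlt, 0) - rho
    # x block of state s
    dx <- numeric(layout$m)
    dx[idx] <- ifelse(side, -den$mlt, 0) + rho
    J[a, layout$idx_x[[s]]] <- dx - S[, l] * dz_dtheta
  }
  list(z = z, J = J, active = active, theta = theta)
}
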