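# Dependency schema: all kinetic constants are linear functions (on log
# scale) of an independent basic vector, so Haldane relationships and
# Wegscheider cycle conditions hold by construction.
#
# Basic variables, in order:
#   g[i]      per metabolite: dimensionless chemical-potential-like term,
#             interpretable as -mu0/RT, with ln Keq = -S' g
#   lnKM[l,i] per (reaction, reactant) pair with nonzero stoichiometry, ln(mM)
#   lnkV[l]   per reaction: log velocity constant, ln(1/s)
#
# Derived constants:
#   ln Keq    = -S' g                         (dimensionless)
#   ln kcat+- = ln kV +- h/2,  h = ln Keq - sum_i S_il lnKM_il  (Haldane)

#' Build the dependency schema for a network
#'
#' @param network an \code{\link{mb_network}}
#' @return an object of class \code{mb_schema} with the basic-variable
#'   layout, the (reaction, metabolite) KM pair table, and the exact linear
#'   expansion matrix mapping the basic vector to all log kinetic constants
#'   (Keq, KM, kcat+, kcat-, kV).  The expansion offset is zero.
#' @export
build_schema <- function(network) {
  S <- network$S
  m <- nrow(S); r <- ncol(S)
  pairs <- do.call(rbind, lapply(seq_len(r), function(l) {
    idx <- network$reactant_index[[l]]
    data.frame(reaction = l, metabolite = idx, stoich = S[idx, l])
  }))
  np <- nrow(pairs)
  idx_g <- seq_len(m)
  idx_km <- m + seq_len(np)
  idx_kv <- m + np + seq_len(r)
  n_basic <- m + np + r
  basic_names <- c(paste0("g:", network$metabolite_ids),
                   paste0("KM:", network$reaction_ids[pairs$reaction], ":",
                          network$metabolite_ids[pairs$metabolite]),
                   paste0("kV:", network$reaction_ids))

  # expansion rows: Keq (r), KM (np), kcat+ (r), kcat- (r), kV (r)
  M <- matrix(0, 4 * r + np, n_basic)
  row_keq <- seq_len(r)
  row_km <- r + seq_len(np)
  row_kcf <- r + np + seq_len(r)
  row_kcb <- r + np + r + seq_len(r)
  row_kv <- r + np + 2 * r + seq_len(r)
  M[row_keq, idx_g] <- -t(S)
  M[cbind(row_km, idx_km)] <- 1
  M[cbind(row_kv, idx_kv)] <- 1
  # h_l = lnKeq_l - sum_i S_il lnKM_il as rows over basic vector
  H <- matrix(0, r, n_basic)
  H[, idx_g] <- -t(S)
  H[cbind(pairs$reaction, idx_km)] <- -pairs$stoich
  M[row_kcf, ] <- M[row_kv, ] + H / 2
  M[row_kcb, ] <- M[row_kv, ] - H / 2
  rownames(M) <- c(paste0("Keq:", network$reaction_ids),
                   paste0("KM:", network$reaction_ids[pairs$reaction], ":",
                          network$metabolite_ids[pairs$metabolite]),
                   paste0("kcat+:", network$reaction_ids),
                   paste0("kcat-:", network$reaction_ids),
                   paste0("kV:", network$reaction_ids))
  colnames(M) <- basic_names

  structure(list(
    network = network, pairs = pairs, n_basic = n_basic,
    basic_names = basic_names,
    idx_g = idx_g, idx_km = idx_km, idx_kv = idx_kv,
    expansion_matrix = M, offset = rep(0, nrow(M)),
    rows = list(keq = row_keq, km = row_km, kcat_fwd = row_kcf,
                kcat_bwd = row_kcb, kv = row_kv)
  ), class = "mb_schema")
}

#' @export
print.mb_schema <- function(x, ...) {
  cat(sprintf("<mb_schema> %d basic variables (%d g, %d lnKM, %d lnkV)\n",
              x$n_basic, length(x$idx_g), length(x$idx_km), length(x$idx_kv)))
  invisible(x)
}

#' Expand a basic vector into the full set of kinetic constants
#'
#' Applies the exact linear map of the schema; the result satisfies the
#' Haldane relationship \code{ln kcat+ - ln kcat- = ln Keq - sum_i S_il
#' ln KM_il} and Wegscheider cycle conditions identically.
#'
#' @param schema an \code{mb_schema}
#' @param q_basic numeric basic vector of length \code{schema$n_basic}
#' @return an object of class \code{mb_constants}: list with \code{ln_Keq},
#'   \code{ln_KM} (named by reaction:metabolite), \code{ln_kcat_fwd},
#'   \code{ln_kcat_bwd}, \code{ln_kV}
#' @export
expand_constants <- function(schema, q_basic) {
  if (length(q_basic) != schema$n_basic)
    stopf("q_basic has length %d, schema expects %d",
          length(q_basic), schema$n_basic)
  q_all <- drop(schema$expansion_matrix %*% q_basic) + schema$offset
  rw <- schema$rows
  net <- schema$network
  rids <- net$reaction_ids
  pair_names <- paste0(rids[schema$pairs$reaction], ":",
                       net$metabolite_ids[schema$pairs$metabolite])
  structure(list(
    ln_Keq = stats::setNames(q_all[rw$keq], rids),
    ln_KM = stats::setNames(q_all[rw$km], pair_names),
    ln_kcat_fwd = stats::setNames(q_all[rw$kcat_fwd], rids),
    ln_kcat_bwd = stats::setNames(q_all[rw$kcat_bwd], rids),
    ln_kV = stats::setNames(q_all[rw$kv], rids),
    pairs = schema$pairs
  ), class = "mb_constants")
}

#' Haldane residual of a constant set
#'
#' @param constants an \code{mb_constants}
#' @param network the matching network
#' @return max absolute residual of
#'   \code{ln kcat+ - ln kcat- - (ln Keq - sum_i S_il ln KM_il)}
#' @export
check_haldane <- function(constants, network) {
  S <- network$S
  p <- constants$pairs
  h <- constants$ln_Keq
  for (k in seq_len(nrow(p)))
    h[p$reaction[k]] <- h[p$reaction[k]] - p$stoich[k] * constants$ln_KM[k]
  max(abs(constants$ln_kcat_fwd - constants$ln_kcat_bwd - h))
}

#' Wegscheider cycle residual of an equilibrium-constant vector
#'
#' Around any stoichiometric cycle (null vector k of the stoichiometric
#' matrix) the log equilibrium constants must sum to zero.  The full S is
#' used: equilibrium constants derive from chemical potentials of all
#' species, so even a pathway passing through clamped metabolites must be
#' consistent.  Returns 0 when the network has no cycles.
#'
#' @param ln_Keq numeric, one value per reaction
#' @param network an \code{\link{mb_network}}
#' @return max absolute cycle residual (0 for an empty null space)
#' @export
check_wegscheider <- function(ln_Keq, network) {
  ns <- null_space(network$S)
  if (ncol(ns) == 0) return(0)
  # scale each cycle vector to max |entry| = 1 so a triangle with
  # ln_Keq = (1,1,1) reports residual 3, not sqrt(3)
  ns <- sweep(ns, 2, apply(abs(ns), 2, max), "/")
  max(abs(drop(t(ns) %*% ln_Keq)))
}

# Orthonormal basis of {k : A k = 0} via SVD
null_space <- function(A, tol = 1e-10) {
  if (nrow(A) == 0) return(diag(ncol(A)))
  sv <- svd(A, nu = 0, nv = ncol(A))
  keep <- sv$d < tol * max(sv$d, 1)
  rank <- sum(sv$d >= tol * max(sv$d, 1))
  if (rank == ncol(A)) return(matrix(0, ncol(A), 0))
  sv$v[, (rank + 1):ncol(A), drop = FALSE]
}
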