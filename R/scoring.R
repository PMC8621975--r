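# Score primitives and the assembled posterior loss R(y).
#
# All priors and data are Gaussian on natural-log scale.  The (q, x) part of
# the posterior is an exact quadratic in y; the enzyme part goes through the
# convex log enzyme-demand function z(y) and is penalised with quad_alpha,
# whose below-mean branch is scaled by the stringency parameter alpha.

#' Diagonal Gaussian specification (log scale)
#'
#' @param mean numeric vector of log-scale means
#' @param sd numeric vector of log-scale standard deviations (> 0),
#'   recycled to the length of \code{mean}
#' @return an \code{mb_gaussian}
#' @export
mb_gaussian <- function(mean, sd) {
  sd <- rep_len(sd, length(mean))
  if (any(!is.na(sd) & sd <= 0)) stopf("standard deviations must be > 0")
  structure(list(mean = mean, sd = sd), class = "mb_gaussian")
}

#' Quadratic score quad(a, Sigma) = a' Sigma^-1 a / 2
#'
#' @param a residual vector
#' @param sigma an [mb_gaussian()] (its \code{sd} supplies the diagonal), a
#'   numeric vector of standard deviations, or a full covariance matrix
#' @return nonnegative scalar score
#' @export
quad <- function(a, sigma) {
  if (inherits(sigma, "mb_gaussian")) sigma <- sigma$sd
  if (is.matrix(sigma)) {
    if (nrow(sigma) != length(a)) stopf("dimension mismatch in quad")
    ch <- tryCatch(chol(sigma), error = function(e)
      stopf("covariance matrix is not positive definite"))
    w <- backsolve(ch, a, transpose = TRUE)
    return(sum(w^2) / 2)
  }
  sigma <- rep_len(sigma, length(a))
  if (length(sigma) != length(a)) stopf("dimension mismatch in quad")
  sum((a / sigma)^2) / 2
}

#' Relaxed quadratic score with stringency parameter alpha
#'
#' Componentwise: \code{(a_i/sigma_i)^2/2} on the non-negative branch and
#' \code{alpha * (a_i/sigma_i)^2/2} on the negative branch.  \code{alpha = 1}
#' recovers [quad()]; \code{alpha = 0} truncates the decreasing branch, which
#' makes the assembled posterior score convex.
#'
#' @param a residual vector
#' @param sigma diagonal standard deviations (or [mb_gaussian()])
#' @param alpha stringency in [0, 1]
#' @return nonnegative scalar score
#' @export
quad_alpha <- function(a, sigma, alpha) {
  if (length(alpha) != 1 || is.na(alpha) || alpha < 0 || alpha > 1)
    stopf("alpha must be a single number in [0, 1]")
  if (inherits(sigma, "mb_gaussian")) sigma <- sigma$sd
  sigma <- rep_len(sigma, length(a))
  w <- ifelse(a < 0, alpha, 1)
  sum(w * (a / sigma)^2) / 2
}

#' Standard-deviation inflation implied by the alpha relaxation
#'
#' Scaling the below-mean branch of the quadratic penalty by alpha is
#' equivalent to assuming a larger standard deviation on that branch.  The
#' factor is measured directly from [quad_alpha()] by matching
#' \code{quad(a, sigma * f) = quad_alpha(a, sigma, alpha)} at a below-mean
#' residual.
#'
#' @param alpha stringency in (0, 1]
#' @return the multiplicative inflation factor of the effective standard
#'   deviation on the below-mean branch (1 at alpha = 1)
#' @export
alpha_sd_inflation <- function(alpha) {
  a <- -1
  sqrt(quad(a, 1) / quad_alpha(a, 1, alpha))
}

#' Combine a Gaussian prior with (possibly missing/duplicate) data
#'
#' Precision-weighted combination: precisions add, the combined mean is the
#' precision-weighted average of the means.  Data are given in long form so
#' that a component may have no measurement (the combination is then the
#' prior) or several (each adds its precision).
#'
#' @param prior an [mb_gaussian()] over n components
#' @param data either an \code{mb_gaussian} of length n whose \code{mean}
#'   may contain \code{NA} (absent), or a data.frame with columns
#'   \code{index}, \code{mean}, \code{sd} (duplicate indices allowed)
#' @return the combined \code{mb_gaussian} (the "preposterior")
#' @export
combine_gaussians <- function(prior, data = NULL) {
  n <- length(prior$mean)
  prec <- 1 / prior$sd^2
  num <- prior$mean / prior$sd^2
  if (!is.null(data)) {
    if (inherits(data, "mb_gaussian")) {
      keep <- which(!is.na(data$mean))
      data <- data.frame(index = keep, mean = data$mean[keep],
                         sd = data$sd[keep])
    }
    if (nrow(data) > 0) {
      if (any(data$index < 1 | data$index > n))
        stopf("data index out of range")
      for (k in seq_len(nrow(data))) {
        i <- data$index[k]
        prec[i] <- prec[i] + 1 / data$sd[k]^2
        num[i] <- num[i] + data$mean[k] / data$sd[k]^2
      }
    }
  }
  mb_gaussian(num / prec, sqrt(1 / prec))
}

#' Assemble the posterior score R(y) and its gradient
#'
#' \code{R(y) = quad(y - y_po, Sigma_po)} over the (q, x) blocks plus
#' \code{quad_alpha(z(y) - z_po, Sigma_po_z)} summed over states, where
#' z(y) are the log enzyme demands of active reactions.  Enzyme terms of
#' zero-flux reactions are omitted.  The (q, x) preposterior is assembled
#' once in the problem (see [mb_problem()]).
#'
#' @param problem an [mb_problem()]
#' @param y full optimisation vector (free and fixed coordinates)
#' @param alpha stringency; defaults to the problem's alpha
#' @return list with \code{total}, \code{parts} (named: qx, and enzyme per
#'   state), \code{gradient} (length(y)), \code{z} per state, \code{alpha}
#' @export
assemble_posterior_score <- function(problem, y, alpha = problem$alpha) {
  pp <- problem$prepost
  lay <- problem$polytope$layout
  if (polytope_margin(problem$polytope, y) < -1e-8)
    stopf("point lies outside the feasible polytope")
  grad <- numeric(lay$n_y)
  # quadratic (q, x) term: 0.5 (w - mu)' P (w - mu) with block structure
  dq <- y[lay$idx_q] - pp$q_mean
  Pdq <- drop(pp$q_prec %*% dq)
  score_qx <- sum(dq * Pdq) / 2
  grad[lay$idx_q] <- Pdq
  for (s in seq_len(lay$n_states)) {
    dx <- y[lay$idx_x[[s]]] - pp$x_mean[, s]
    score_qx <- score_qx + sum((dx / pp$x_sd[, s])^2) / 2
    grad[lay$idx_x[[s]]] <- dx / pp$x_sd[, s]^2
  }
  parts <- c(qx = score_qx)
  zs <- vector("list", lay$n_states)
  for (s in seq_len(lay$n_states)) {
    ze <- log_enzyme_demand_and_gradient(problem$schema, y, problem$fluxes,
                                         s, lay)
    zs[[s]] <- ze
    if (length(ze$active) == 0) { parts <- c(parts, 0); next }
    res <- ze$z - pp$z_mean[ze$active, s]
    sd <- pp$z_sd[ze$active, s]
    parts <- c(parts, quad_alpha(res, sd, alpha))
    w <- ifelse(res < 0, alpha, 1) * res / sd^2
    grad <- grad + drop(crossprod(ze$J, w))
  }
  names(parts) <- c("qx", paste0("enzyme:s", seq_len(lay$n_states)))
  list(total = sum(parts), parts = parts, gradient = grad, z = zs,
       alpha = alpha)
}
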