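# Numerically stable helpers used throughout the package.  Optimisation
# probes polytope corners, so all rate-law algebra is done on log scale.

#' @noRd
log1pexp <- function(u) {
  # log(1 + exp(u)) without overflow
  out <- u
  small <- u <= 18
  out[small] <- log1p(exp(u[small]))
  big <- u > 18 & u <= 33.3
  out[big] <- u[big] + exp(-u[big])
  out
}

#' @noRd
log1mexp <- function(t) {
  # log(1 - exp(-t)) for t > 0 (Maechler's two-branch form)
  out <- t
  lo <- t <= log(2)
  out[lo] <- log(-expm1(-t[lo]))
  out[!lo] <- log1p(-exp(-t[!lo]))
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Geometric-scale helpers
#'
#' A lognormal quantity with median \code{m} and geometric standard deviation
#' \code{gsd} has log-mean \code{log(m)} and log-sd \code{log(gsd)}.
#' @param gsd geometric standard deviation (> 1 for a proper distribution)
#' @return log-scale standard deviation
#' @export
gsd_to_sd <- function(gsd) {
  if (any(gsd < 1)) stopf("geometric standard deviations must be >= 1")
  log(gsd)
}

#' @rdname gsd_to_sd
#' @param sd log-scale standard deviation
#' @export
sd_to_gsd <- function(sd) exp(sd)
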