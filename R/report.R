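# Recovery metrics: log-scale Pearson correlation and the geometric
# standard deviation of residuals (exp of the root-mean-square log
# residual), per quantity type, pooled across states.

#' Pearson correlation on log scale
#' @param a,b positive vectors of equal length >= 3
#' @return correlation of (log a, log b)
#' @export
log_pearson <- function(a, b) {
  if (length(a) != length(b)) stopf("length mismatch")
  if (length(a) < 3) stopf("need at least 3 pairs")
  if (any(a <= 0) || any(b <= 0)) stopf("values must be positive")
  la <- log(a); lb <- log(b)
  if (stats::sd(la) == 0 || stats::sd(lb) == 0)
    stopf("correlation undefined for constant input")
  stats::cor(la, lb)
}

#' Geometric standard deviation of residuals
#' @param a,b positive vectors of equal length
#' @return \code{exp(sqrt(mean((log a - log b)^2)))}; 1 means agreement
#' @export
geometric_sd_residuals <- function(a, b) {
  if (length(a) != length(b)) stopf("length mismatch")
  if (any(a <= 0) || any(b <= 0)) stopf("values must be positive")
  exp(sqrt(mean((log(a) - log(b))^2)))
}

#' Compare a balancing result with a synthetic truth bundle
#'
#' Computes per-quantity-type recovery metrics (log-scale Pearson
#' correlation, geometric standard deviation of residuals, n) pooled across
#' states, flags each type as \code{fitted} (data present in the scenario)
#' or \code{predicted}, and returns the underlying scatter rows for
#' external plotting.  Enzymes of zero-flux reactions are excluded.
#'
#' @param truth the \code{truth} element of [make_scenario_dataset()]
#' @param result an \code{mb_result}
#' @param scenario "S1", "S1K", or "S2" (sets the fitted/predicted flags)
#' @return list(metrics, scatter): data frames
#' @export
build_report <- function(truth, result, scenario = "S1") {
  est <- result$constants
  act <- !is.na(result$z)
  types <- list(
    `metabolite concentration` = list(true = exp(as.vector(truth$x)),
                                      est = exp(as.vector(result$x)),
                                      fitted = TRUE),
    `enzyme concentration` = list(true = truth$e[act],
                                  est = exp(result$z[act]),
                                  fitted = TRUE),
    Keq = list(true = exp(truth$constants$ln_Keq), est = exp(est$ln_Keq),
               fitted = scenario %in% c("S1", "S1K")),
    kcat = list(true = exp(c(truth$constants$ln_kcat_fwd,
                             truth$constants$ln_kcat_bwd)),
                est = exp(c(est$ln_kcat_fwd, est$ln_kcat_bwd)),
                fitted = scenario == "S1"),
    KM = list(true = exp(truth$constants$ln_KM), est = exp(est$ln_KM),
              fitted = scenario == "S1"))
  metrics <- do.call(rbind, lapply(names(types), function(nm) {
    tt <- types[[nm]]
    if (length(tt$true) != length(tt$est)) stopf("index mismatch for %s", nm)
    data.frame(quantity = nm,
               r_log = log_pearson(tt$true, tt$est),
               gsd = geometric_sd_residuals(tt$true, tt$est),
               n = length(tt$true),
               role = if (tt$fitted) "fitted" else "predicted",
               stringsAsFactors = FALSE)
  }))
  scatter <- do.call(rbind, lapply(names(types), function(nm) {
    tt <- types[[nm]]
    data.frame(quantity = nm, true = tt$true, estimated = tt$est,
               role = if (tt$fitted) "fitted" else "predicted",
               stringsAsFactors = FALSE)
  }))
  list(metrics = metrics, scatter = scatter)
}
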