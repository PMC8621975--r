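# Tab-delimited I/O in the SBtab-flavoured dialect: data tables with
# !-prefixed column headers, flux tables in long format, and result writers.

#' Read a data table
#'
#' Columns \code{!QuantityType}, \code{!Reaction}, \code{!Compound},
#' \code{!State}, \code{!Mean}, \code{!GeometricStd}; values on linear
#' scale.
#' @param path file path
#' @return a data.frame usable as [mb_problem()] \code{data}
#' @export
read_data_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#", na.strings = c("NA", ""))
  need <- c("!QuantityType", "!Mean", "!GeometricStd")
  if (!all(need %in% names(df)))
    stopf("data table must have columns %s", paste(need, collapse = ", "))
  mb_data(df[["!QuantityType"]], df[["!Reaction"]] %||% NA,
          df[["!Compound"]] %||% NA, df[["!State"]] %||% NA,
          df[["!Mean"]], df[["!GeometricStd"]])
}

#' @rdname read_data_table
#' @param data a long-format data table
#' @export
write_data_table <- function(data, path) {
  out <- data
  names(out) <- paste0("!", names(out))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flux table (long format: !Reaction, !State, !Mean)
#' @param path file path
#' @param network the network the reactions belong to
#' @return flux matrix, reactions x states
#' @export
read_fluxes <- function(path, network) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("!Reaction", "!State", "!Mean")
  if (!all(need %in% names(df)))
    stopf("flux table must have columns %s", paste(need, collapse = ", "))
  states <- sort(unique(as.integer(df[["!State"]])))
  V <- matrix(0, ncol(network$S), length(states),
              dimnames = list(network$reaction_ids, paste0("s", states)))
  for (k in seq_len(nrow(df))) {
    l <- match(df[["!Reaction"]][k], network$reaction_ids)
    if (is.na(l)) stopf("unknown reaction '%s' in flux table", df[["!Reaction"]][k])
    V[l, match(as.integer(df[["!State"]][k]), states)] <- df[["!Mean"]][k]
  }
  V
}

#' @rdname read_fluxes
#' @param fluxes flux matrix (reactions x states)
#' @export
write_fluxes <- function(fluxes, path, network) {
  df <- expand.grid(l = seq_len(nrow(fluxes)), s = seq_len(ncol(fluxes)))
  utils::write.table(
    data.frame(`!Reaction` = network$reaction_ids[df$l], `!State` = df$s,
               `!Mean` = fluxes[cbind(df$l, df$s)], check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a balancing result to a directory
#'
#' Emits \code{constants.tsv} (balanced kinetic constants, linear scale),
#' \code{state_<quantity>.tsv} tables (concentrations in mM, enzyme levels
#' in mM with empty cells for zero-flux reactions, forces in RT units), and
#' \code{score.tsv} with the score decomposition and diagnostics.
#'
#' @param result an \code{mb_result}
#' @param dir output directory (created if needed)
#' @return invisibly, \code{dir}
#' @export
write_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- result$problem$network
  cst <- result$constants
  ctab <- rbind(
    data.frame(QuantityType = "equilibrium constant", Reaction = net$reaction_ids,
               Compound = NA, Value = exp(cst$ln_Keq)),
    data.frame(QuantityType = "catalytic rate constant (forward)",
               Reaction = net$reaction_ids, Compound = NA,
               Value = exp(cst$ln_kcat_fwd)),
    data.frame(QuantityType = "catalytic rate constant (backward)",
               Reaction = net$reaction_ids, Compound = NA,
               Value = exp(cst$ln_kcat_bwd)),
    data.frame(QuantityType = "velocity constant", Reaction = net$reaction_ids,
               Compound = NA, Value = exp(cst$ln_kV)),
    data.frame(QuantityType = "Michaelis constant",
               Reaction = net$reaction_ids[cst$pairs$reaction],
               Compound = net$metabolite_ids[cst$pairs$metabolite],
               Value = exp(cst$ln_KM)))
  names(ctab) <- paste0("!", names(ctab))
  utils::write.table(ctab, file.path(dir, "constants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  wr <- function(M, nm) utils::write.table(
    data.frame(`!ID` = rownames(M), M, check.names = FALSE),
    file.path(dir, nm), sep = "\t", quote = FALSE, row.names = FALSE)
  wr(exp(result$x), "state_concentrations.tsv")
  wr(exp(result$z), "state_enzymes.tsv")
  wr(result$theta, "state_forces.tsv")
  sc <- data.frame(term = c(names(result$score), "total", "alpha",
                            "grad_norm", "kkt_residual", "converged"),
                   value = c(unname(result$score), result$total, result$alpha,
                             result$diagnostics$grad_norm,
                             result$diagnostics$kkt_residual,
                             as.numeric(result$diagnostics$converged)))
  utils::write.table(sc, file.path(dir, "score.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
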