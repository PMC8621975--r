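# Metabolic network container: stoichiometric matrix plus metadata.
# Internal metabolites are balanced at steady state; external ones are
# clamped boundary species (their concentrations are still estimated unless
# fixed explicitly).

#' Construct a metabolic network
#'
#' @param S integer stoichiometric matrix, metabolites x reactions
#'   (negative entries = consumed, positive = produced).
#' @param metabolite_ids,reaction_ids character identifiers; defaults taken
#'   from \code{dimnames(S)}.
#' @param is_internal logical per metabolite; internal metabolites are mass
#'   balanced at steady state, external ones are clamped.
#' @return an object of class \code{mb_network} with fields \code{S},
#'   \code{metabolite_ids}, \code{reaction_ids}, \code{is_internal}, and
#'   \code{reactant_index} (per reaction, the indices of metabolites with
#'   nonzero stoichiometry).
#' @export
mb_network <- function(S, metabolite_ids = rownames(S),
                       reaction_ids = colnames(S),
                       is_internal = rep(TRUE, nrow(S))) {
  S <- as.matrix(S)
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("M", seq_len(nrow(S)))
  if (is.null(reaction_ids)) reaction_ids <- paste0("R", seq_len(ncol(S)))
  if (anyDuplicated(metabolite_ids)) stopf("duplicate metabolite ids")
  if (anyDuplicated(reaction_ids)) stopf("duplicate reaction ids")
  if (length(metabolite_ids) != nrow(S) || length(reaction_ids) != ncol(S))
    stopf("id lengths do not match S dimensions")
  if (length(is_internal) != nrow(S))
    stopf("is_internal length does not match the number of metabolites")
  if (any(S != round(S)))
    stopf("stoichiometric coefficients must be integers")
  if (any(colSums(S != 0) == 0))
    stopf("reaction(s) with all-zero stoichiometry: %s",
          paste(reaction_ids[colSums(S != 0) == 0], collapse = ", "))
  if (any(colSums(S < 0) == 0))
    stopf("reaction(s) without a substrate: %s",
          paste(reaction_ids[colSums(S < 0) == 0], collapse = ", "))
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  structure(list(
    S = S,
    metabolite_ids = metabolite_ids,
    reaction_ids = reaction_ids,
    is_internal = as.logical(is_internal),
    reactant_index = lapply(seq_len(ncol(S)), function(l) which(S[, l] != 0))
  ), class = "mb_network")
}

#' @export
print.mb_network <- function(x, ...) {
  cat(sprintf("<mb_network> %d metabolites (%d internal), %d reactions\n",
              nrow(x$S), sum(x$is_internal), ncol(x$S)))
  invisible(x)
}

# Parse one reaction formula like "A + 2 B <=> C".  Integer coefficients
# only; the two sides are separated by "<=>".
parse_formula <- function(formula, id = "?") {
  if (is.na(formula) || !nzchar(trimws(formula)))
    stopf("reaction '%s': empty formula", id)
  formula <- trimws(formula)
  sides <- strsplit(formula, "<=>", fixed = TRUE)[[1]]
  if (length(sides) != 2 && !grepl("<=>", formula))
    stopf("reaction '%s': formula must contain '<=>'", id)
  parse_side <- function(side) {
    side <- trimws(side)
    if (!nzchar(side)) return(list(met = character(), coef = integer()))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    met <- character(0); coef <- integer(0)
    for (tm in terms) {
      if (!nzchar(tm)) stopf("reaction '%s': empty term in formula", id)
      m <- regmatches(tm, regexec("^([0-9]+(?:\\.[0-9]+)?\\s+)?(\\S+)$", tm))[[1]]
      if (length(m) == 0) stopf("reaction '%s': cannot parse term '%s'", id, tm)
      cf <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
      if (cf != round(cf))
        stopf("reaction '%s': non-integer stoichiometric coefficient '%s'",
              id, trimws(m[2]))
      met <- c(met, m[3]); coef <- c(coef, as.integer(cf))
    }
    list(met = met, coef = coef)
  }
  lhs <- parse_side(sides[1])
  rhs <- parse_side(if (length(sides) >= 2) sides[2] else "")
  if (length(lhs$met) == 0)
    stopf("reaction '%s': no substrate side", id)
  list(lhs = lhs, rhs = rhs)
}

#' Read a metabolic network from tab-delimited tables
#'
#' The reaction table must have columns \code{!ID} and
#' \code{!ReactionFormula} (e.g. \code{"A + B <=> 2 C"}).  An optional
#' metabolite table with columns \code{!ID} and \code{!IsConstant} marks
#' external (clamped) metabolites; without it all metabolites are internal.
#'
#' @param reactions_path path to the reaction table
#' @param metabolites_path optional path to the metabolite table
#' @return an \code{\link{mb_network}}
#' @export
read_network <- function(reactions_path, metabolites_path = NULL) {
  rt <- utils::read.delim(reactions_path, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("!ID", "!ReactionFormula")
  if (!all(need %in% names(rt)))
    stopf("reaction table must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(rt[["!ID"]])) stopf("duplicate reaction ids in table")
  parsed <- lapply(seq_len(nrow(rt)), function(i) {
    tryCatch(parse_formula(rt[["!ReactionFormula"]][i], rt[["!ID"]][i]),
             error = function(e) stopf("line %d: %s", i + 1, conditionMessage(e)))
  })
  mets <- unique(unlist(lapply(parsed, function(p) c(p$lhs$met, p$rhs$met))))
  S <- matrix(0L, length(mets), nrow(rt), dimnames = list(mets, rt[["!ID"]]))
  for (i in seq_along(parsed)) {
    p <- parsed[[i]]
    S[p$lhs$met, i] <- S[p$lhs$met, i] - p$lhs$coef
    S[p$rhs$met, i] <- S[p$rhs$met, i] + p$rhs$coef
  }
  is_internal <- rep(TRUE, length(mets))
  if (!is.null(metabolites_path)) {
    mt <- utils::read.delim(metabolites_path, check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "#")
    if (!all(c("!ID", "!IsConstant") %in% names(mt)))
      stopf("metabolite table must have columns !ID, !IsConstant")
    ext <- mt[["!ID"]][as.logical(mt[["!IsConstant"]])]
    unknown <- setdiff(mt[["!ID"]], mets)
    if (length(unknown))
      stopf("metabolite table lists unknown metabolites: %s",
            paste(unknown, collapse = ", "))
    is_internal[mets %in% ext] <- FALSE
  }
  mb_network(S, mets, rt[["!ID"]], is_internal)
}

#' Write a network to the tab-delimited dialect read by [read_network()]
#' @param network an \code{mb_network}
#' @param reactions_path,metabolites_path output paths
#' @return invisibly, the network
#' @export
write_network <- function(network, reactions_path, metabolites_path = NULL) {
  fm <- vapply(seq_along(network$reaction_ids), function(l) {
    s <- network$S[, l]
    term <- function(idx) paste(vapply(idx, function(i) {
      cf <- abs(s[i])
      if (cf == 1) network$metabolite_ids[i]
      else paste(cf, network$metabolite_ids[i])
    }, ""), collapse = " + ")
    paste(term(which(s < 0)), "<=>", term(which(s > 0)))
  }, "")
  utils::write.table(
    data.frame(`!ID` = network$reaction_ids, `!ReactionFormula` = fm,
               check.names = FALSE),
    reactions_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metabolites_path))
    utils::write.table(
      data.frame(`!ID` = network$metabolite_ids,
                 `!IsConstant` = !network$is_internal, check.names = FALSE),
      metabolites_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(network)
}

#' Small example network topologies
#'
#' \code{"chain"} is a linear pathway X0 <-> M1 <-> ... <-> Xn with clamped
#' end metabolites; \code{"branch"} adds a branch reaction from the middle
#' metabolite to an extra external sink; \code{"triangle"} is the closed
#' three-reaction cycle A -> B -> C -> A (all internal) used to exercise
#' Wegscheider cycle conditions.
#'
#' @param type one of \code{"chain"}, \code{"branch"}, \code{"triangle"}
#' @param n_reactions number of reactions (chain/branch)
#' @return an \code{\link{mb_network}}
#' @export
example_network <- function(type = c("chain", "branch", "triangle"),
                            n_reactions = 3) {
  type <- match.arg(type)
  if (type == "triangle") {
    S <- matrix(c(-1, 1, 0, 0, -1, 1, 1, 0, -1), 3, 3,
                dimnames = list(c("A", "B", "C"), c("R1", "R2", "R3")))
    return(mb_network(S))
  }
  if (n_reactions < 2) stopf("need at least 2 reactions")
  n_met <- n_reactions + 1
  mets <- c("Xin", paste0("M", seq_len(n_met - 2)), "Xout")
  S <- matrix(0L, n_met, n_reactions,
              dimnames = list(mets, paste0("R", seq_len(n_reactions))))
  for (l in seq_len(n_reactions)) {
    S[l, l] <- -1L
    S[l + 1, l] <- 1L
  }
  is_internal <- c(FALSE, rep(TRUE, n_met - 2), FALSE)
  if (type == "branch") {
    mid <- ceiling(n_met / 2)
    S <- cbind(S, Rb = 0L)
    S <- rbind(S, Xbr = 0L)
    S[mid, n_reactions + 1] <- -1L
    S["Xbr", n_reactions + 1] <- 1L
    colnames(S)[n_reactions + 1] <- "Rb"
    is_internal <- c(is_internal, FALSE)
  }
  mb_network(S, rownames(S), colnames(S), is_internal)
}
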