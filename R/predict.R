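## Cautious prediction: a statement holds as a prediction when it holds in
## every consistent labeling.  Rather than enumerating the (possibly
## exponential) labeling set, the realized label set of each node is probed
## with at most three satisfiability queries: one witness labeling supplies
## one realized value per node for free, and each remaining value is tested
## by pinning it.

realized_sets <- function(graph, profile, notion, pinned_base = NULL) {
  inst <- build_instance(graph, profile, notion, pinned = pinned_base)
  witness <- search_labelings(inst, "exists")
  if (is.null(witness)) return(NULL)
  n <- inst$n
  realized <- lapply(seq_len(n), function(i) witness[[i]])
  # propagation on the root gives a cheap upper bound on realizable values
  root_cand <- propagate_cand(inst, inst$cand)
  for (i in seq_len(n)) {
    for (v in setdiff(root_cand[[i]], realized[[i]])) {
      pin <- stats::setNames(v, inst$nodes[[i]])
      inst_v <- build_instance(graph, profile, notion,
                              pinned = c(pinned_base, as.list(pin)))
      if (!is.null(search_labelings(inst_v, "exists"))) {
        realized[[i]] <- c(realized[[i]], v)
      }
    }
  }
  stats::setNames(realized, inst$nodes)
}

#' Cautious predictions over the consistent labelings
#'
#' For each node, the set of labels it takes across all consistent labelings
#' is classified into a strong prediction (`"+"`, `"-"`, `"0"`: same label in
#' every admissible behavior), a weak prediction (`"w+"`, `"w-"`, `"chg"`:
#' one behavior excluded) or no prediction (`"no"`).  Measured nodes are
#' included in the map; downstream statistics restrict to unmeasured nodes.
#'
#' @inheritParams violations
#' @return named character vector over all graph nodes (a prediction map).
#' @seealso [predict_under_mcos()] for inconsistent instances.
#' @export
predict_labels <- function(graph, profile, notion = "FSP") {
  rs <- realized_sets(graph, profile, notion)
  if (is.null(rs)) {
    stop("graph and profile are inconsistent under ", notion,
         "; use predict_under_mcos() for prediction under minimal repair")
  }
  vapply(rs, classify, character(1))
}

prediction_map_from_sets <- function(sets) vapply(sets, classify, character(1))
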