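## Repair of inconsistent instances.
##
## A correction adds an artificial always-active input influence (node
## pinned to +, edge sign carries the direction) onto a non-input node.
## Minimal correction sets (MCoS) are the minimum-cardinality sets of such
## additions restoring consistency; their size divided by the number of
## observations is the inconsistency index.  SCEN-FIT instead keeps the
## topology fixed and counts the minimum number of observations that must be
## discarded for a propagation-consistent labeling to exist.

artificial_name <- function(node, sign) {
  paste0("..r", ifelse(sign > 0L, "p", "m"), ".", node)
}

as_repair_set <- function(repair) {
  if (is.null(repair) || (is.data.frame(repair) && nrow(repair) == 0L) || length(repair) == 0L) {
    return(data.frame(node = character(), sign = integer()))
  }
  if (!is.data.frame(repair)) {
    # list of c(node, sign) pairs
    repair <- data.frame(
      node = vapply(repair, function(p) as.character(p[[1]]), character(1)),
      sign = vapply(repair, function(p) {
        s <- p[[2]]
        if (is.character(s)) s <- c(`+` = 1L, `-` = -1L)[[s]]
        as.integer(s)
      }, integer(1))
    )
  }
  repair$node <- as.character(repair$node)
  if (is.character(repair$sign)) {
    repair$sign <- unname(c(`+` = 1L, `-` = -1L)[repair$sign])
  }
  repair$sign <- as.integer(repair$sign)
  if (!all(repair$sign %in% c(1L, -1L))) stop("repair signs must be +1 or -1")
  if (anyDuplicated(paste(repair$node, repair$sign))) stop("duplicate (node, sign) pair in repair set")
  repair[order(repair$node, -repair$sign), , drop = FALSE]
}

#' Apply a repair set to an instance
#'
#' For each `(node, sign)` correction a fresh artificial node is added, made
#' an input, observed as a certain increase (so it is always active), and
#' connected to the target by an edge of the given sign.  Artificial nodes
#' are flagged on the graph so that prediction and metrics ignore them.
#'
#' @param graph an [interaction_graph()].
#' @param profile an [experimental_profile()].
#' @param repair a data.frame with columns `node`, `sign` (or a list of
#'   `(node, sign)` pairs); targets must be non-input graph nodes.
#' @return list with components `graph` and `profile`, the repaired
#'   instance.
#' @export
apply_repair <- function(graph, profile, repair) {
  stopifnot(inherits(graph, "interaction_graph"), inherits(profile, "experimental_profile"))
  repair <- as_repair_set(repair)
  if (nrow(repair) == 0L) return(list(graph = graph, profile = profile))
  unknown <- setdiff(repair$node, graph$nodes)
  if (length(unknown)) stop("repair target(s) not in graph: ", paste(unknown, collapse = ", "))
  on_input <- intersect(repair$node, profile$inputs)
  if (length(on_input)) {
    stop("repair target(s) are input nodes: ", paste(on_input, collapse = ", "))
  }
  art <- artificial_name(repair$node, repair$sign)
  if (any(art %in% graph$nodes)) stop("artificial node name collision")
  new_edges <- data.frame(source = art, target = repair$node, sign = repair$sign)
  g2 <- interaction_graph(rbind(graph$edges, new_edges), nodes = c(graph$nodes, art))
  g2$artificial <- sort(c(graph$artificial, art))
  p2 <- experimental_profile(
    discrete = c(profile$discrete, stats::setNames(rep("+", length(art)), art)),
    inputs = c(profile$inputs, art),
    raw = NULL
  )
  list(graph = g2, profile = p2)
}

repair_candidates <- function(graph, profile) {
  targets <- setdiff(graph$nodes, union(profile$inputs, graph$artificial))
  targets <- sort(targets)
  data.frame(
    node = rep(targets, each = 2L),
    sign = rep(c(1L, -1L), times = length(targets))
  )
}

#' Minimal correction sets
#'
#' Iterative deepening over the repair cardinality k = 0, 1, 2, ...: at each
#' k every k-subset of the candidate space (non-input nodes times both
#' signs) is tested for consistency after repair; the first feasible k is
#' the MCoS size and all feasible k-subsets are returned.  Every
#' inconsistency is repairable by adding influences, so the search
#' terminates (a configurable cap guards against runaway instances).
#'
#' @inheritParams violations
#' @param max_size cap on the repair cardinality searched (default 32).
#' @return list of class `mcos_result` with components `size` (integer),
#'   `sets` (list of data.frames `node`, `sign`, all minimum-cardinality
#'   correction sets) and `index` (size divided by the number of
#'   observations; `NA` when nothing is measured).
#' @export
mcos <- function(graph, profile, notion = "FSP", max_size = 32L) {
  n_obs <- length(profile$measured)
  if (is_consistent(graph, profile, notion)) {
    return(structure(
      list(size = 0L, sets = list(data.frame(node = character(), sign = integer())),
           index = if (n_obs) 0 else NA_real_),
      class = "mcos_result"
    ))
  }
  cand <- repair_candidates(graph, profile)
  for (k in seq_len(min(max_size, nrow(cand)))) {
    hits <- list()
    combos <- utils::combn(nrow(cand), k)
    for (ci in seq_len(ncol(combos))) {
      r <- cand[combos[, ci], , drop = FALSE]
      rep_inst <- apply_repair(graph, profile, r)
      if (is_consistent(rep_inst$graph, rep_inst$profile, notion)) {
        rownames(r) <- NULL
        hits[[length(hits) + 1L]] <- r
      }
    }
    if (length(hits)) {
      return(structure(
        list(size = k, sets = hits,
             index = if (n_obs) k / n_obs else NA_real_),
        class = "mcos_result"
      ))
    }
  }
  stop(errorCondition(
    sprintf("no correction set of size <= %d restores consistency", max_size),
    class = c("sc_limit_error", "error", "condition")
  ))
}

#' @export
print.mcos_result <- function(x, ...) {
  cat(sprintf("Minimal correction sets: size %d, %d set(s)", x$size, length(x$sets)))
  if (!is.na(x$index)) cat(sprintf(", inconsistency index %.4g", x$index))
  cat("\n")
  if (x$size > 0L) {
    for (s in utils::head(x$sets, 10L)) {
      cat("  {", paste(sprintf("%s:%s", s$node, ifelse(s$sign > 0L, "+", "-")), collapse = ", "), "}\n")
    }
    if (length(x$sets) > 10L) cat(sprintf("  ... and %d more sets\n", length(x$sets) - 10L))
  }
  invisible(x)
}

#' Inconsistency index
#'
#' Size of the minimal correction set divided by the number of observations
#' in the experiment; 0 for consistent instances.
#'
#' @inheritParams mcos
#' @return real in `[0, 1]` (typically; can exceed 1 on pathological
#'   instances with very few observations).
#' @export
inconsistency_index <- function(graph, profile, notion = "FSP", max_size = 32L) {
  if (length(profile$measured) == 0L) stop("inconsistency index undefined: no observations")
  mcos(graph, profile, notion, max_size = max_size)$index
}

#' Cautious prediction under minimal repair
#'
#' When graph and data are inconsistent, predictions are still possible:
#' a statement is predicted when it holds in every consistent labeling of
#' every minimum-cardinality repaired instance (no minimal repair is
#' favored).  On consistent instances this degenerates to
#' [predict_labels()].
#'
#' @inheritParams mcos
#' @return named character prediction map over the original (non-artificial)
#'   graph nodes.
#' @export
predict_under_mcos <- function(graph, profile, notion = "FSP", max_size = 32L) {
  m <- mcos(graph, profile, notion, max_size = max_size)
  orig_nodes <- setdiff(graph$nodes, graph$artificial)
  union_sets <- stats::setNames(vector("list", length(orig_nodes)), orig_nodes)
  for (r in m$sets) {
    rep_inst <- apply_repair(graph, profile, r)
    rs <- realized_sets(rep_inst$graph, rep_inst$profile, notion)
    for (nm in orig_nodes) {
      union_sets[[nm]] <- union(union_sets[[nm]], rs[[nm]])
    }
  }
  vapply(union_sets, classify, character(1))
}

## ---- SCEN-FIT -------------------------------------------------------------

#' Minimal observation corrections (SCEN-FIT)
#'
#' Finds the labelings that satisfy the notion's propagation constraints
#' (C2, and C3/C4 as applicable) for all nodes while being as close as
#' possible to the measurements: the cost of a labeling is the number of
#' measured nodes whose label falls outside the set admitted by their
#' observation (uncertain observations admit two labels at cost 0).
#' `corrections` is 0 exactly when the instance is consistent.
#'
#' @inheritParams violations
#' @param max_witnesses cap on the number of cost-minimal labelings
#'   collected (default `1e5`).
#' @return list with components `corrections` (non-negative integer) and
#'   `witnesses` (list of named integer labelings attaining the minimum, in
#'   deterministic lexicographic order).
#' @export
scenfit <- function(graph, profile, notion = "FSP", max_witnesses = 1e5) {
  inst <- build_instance(graph, profile, notion, use_obs = FALSE)
  n <- inst$n
  # admitted label sets from observations, by node index (NULL = unmeasured)
  admitted <- vector("list", n)
  meas <- intersect(profile$measured, graph$nodes)
  for (m in meas) admitted[[inst$idx[[m]]]] <- allowed_labels(profile$discrete[[m]])

  best <- Inf
  witnesses <- list()
  truncated <- FALSE

  mismatch_cost <- function(cand) {
    # lower bound: nodes whose whole candidate set lies outside the admitted set
    cost <- 0L
    for (i in seq_len(n)) {
      if (!is.null(admitted[[i]]) && !any(cand[[i]] %in% admitted[[i]])) cost <- cost + 1L
    }
    cost
  }

  dfs <- function(cand, pos) {
    if (mismatch_cost(cand) > best) return()
    while (pos <= n && length(cand[[pos]]) == 1L) pos <- pos + 1L
    if (pos > n) {
      lab <- vapply(cand, `[[`, integer(1), 1L)
      if (nrow(violations_int(inst, lab)) == 0L) {
        cost <- mismatch_cost(cand)
        if (cost < best) {
          best <<- cost
          witnesses <<- list(labeling_named(inst, lab))
          truncated <<- FALSE
        } else if (cost == best) {
          if (length(witnesses) < max_witnesses) {
            witnesses[[length(witnesses) + 1L]] <<- labeling_named(inst, lab)
          } else {
            truncated <<- TRUE
          }
        }
      }
      return()
    }
    for (v in NODE_LABELS[NODE_LABELS %in% cand[[pos]]]) {
      cand2 <- cand
      cand2[[pos]] <- v
      cand2 <- propagate_cand(inst, cand2)
      if (!is.null(cand2)) dfs(cand2, pos + 1L)
    }
  }
  cand0 <- propagate_cand(inst, inst$cand)
  if (!is.null(cand0)) dfs(cand0, 1L)
  if (!is.finite(best)) {
    # cannot happen: the all-zero labeling always satisfies C2-C4 when every
    # predecessor-free non-input can be labeled 0; guarded anyway
    stop("no labeling satisfies the propagation constraints")
  }
  if (truncated) {
    warning(sprintf("witness list truncated at %g labelings", max_witnesses))
  }
  list(corrections = as.integer(best), witnesses = witnesses)
}
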