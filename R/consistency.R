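## Consistency engine.
##
## An instance compiles graph + profile + notion into index-based structures:
## nodes in sorted order, per-node incoming edge lists, input flags and
## per-node candidate label sets seeded from the observations (Constraint 1).
## Search is depth-first over nodes in sorted order with value order + , 0, -
## (so enumeration is lexicographic), interleaved with two sound pruning
## passes: arc-consistency on Constraints 2/3 and possible-foundedness for
## Constraint 4.  Every leaf is re-checked against the full constraint
## definitions, so pruning only affects speed, never correctness.

NOTIONS <- c("WP", "SP", "FWP", "FSP")

check_notion <- function(notion) {
  if (!is.character(notion) || length(notion) != 1L || !notion %in% NOTIONS) {
    stop("notion must be one of ", paste(NOTIONS, collapse = ", "))
  }
  notion
}

notion_has_c3 <- function(notion) notion %in% c("SP", "FSP")
notion_has_c4 <- function(notion) notion %in% c("FWP", "FSP")

## ---- instance compilation -------------------------------------------------

build_instance <- function(graph, profile, notion, pinned = NULL, use_obs = TRUE) {
  stopifnot(inherits(graph, "interaction_graph"))
  stopifnot(inherits(profile, "experimental_profile"))
  check_notion(notion)
  nodes <- graph$nodes # already sorted
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)

  unknown_inputs <- setdiff(profile$inputs, nodes)
  if (length(unknown_inputs)) {
    stop("input node(s) not in graph: ", paste(unknown_inputs, collapse = ", "))
  }
  is_input <- nodes %in% profile$inputs

  e <- graph$edges
  pred_j <- vector("list", n)
  pred_s <- vector("list", n)
  for (i in seq_len(n)) {
    pred_j[[i]] <- integer()
    pred_s[[i]] <- integer()
  }
  if (nrow(e)) {
    ti <- idx[e$target]
    si <- idx[e$source]
    for (k in seq_len(nrow(e))) {
      t <- ti[[k]]
      pred_j[[t]] <- c(pred_j[[t]], si[[k]])
      pred_s[[t]] <- c(pred_s[[t]], e$sign[[k]])
    }
  }

  cand <- rep(list(NODE_LABELS), n)
  if (use_obs && length(profile$measured)) {
    meas <- intersect(profile$measured, nodes)
    for (m in meas) {
      cand[[idx[[m]]]] <- allowed_labels(profile$discrete[[m]])
    }
  }
  if (!is.null(pinned)) {
    pv <- pinned
    if (is.character(pv)) pv <- stats::setNames(token_to_node_label(unname(pinned)), names(pinned))
    unknown <- setdiff(names(pv), nodes)
    if (length(unknown)) stop("pinned node(s) not in graph: ", paste(unknown, collapse = ", "))
    for (nm in names(pv)) {
      i <- idx[[nm]]
      cand[[i]] <- intersect(cand[[i]], as.integer(pv[[nm]]))
    }
  }

  list(
    nodes = nodes, n = n, idx = idx, is_input = is_input,
    pred_j = pred_j, pred_s = pred_s, cand = cand, notion = notion
  )
}

## ---- propagation ----------------------------------------------------------

# Sound pruning: removes candidate values that cannot occur in any solution.
# Returns the pruned candidate list, or NULL if some node has no candidate.
propagate_cand <- function(inst, cand) {
  n <- inst$n
  c3 <- notion_has_c3(inst$notion)
  c4 <- notion_has_c4(inst$notion)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      if (inst$is_input[[i]]) next
      ci <- cand[[i]]
      if (length(ci) == 0L) return(NULL)
      js <- inst$pred_j[[i]]
      ss <- inst$pred_s[[i]]
      # Constraint 2 support for +/-: some edge can deliver a matching influence
      for (v in c(1L, -1L)) {
        if (!v %in% ci) next
        supported <- FALSE
        if (length(js)) {
          for (k in seq_along(js)) {
            if ((v * ss[[k]]) %in% cand[[js[[k]]]]) { supported <- TRUE; break }
          }
        }
        if (!supported) {
          ci <- setdiff(ci, v)
          changed <- TRUE
        }
      }
      # Constraint 3 support for 0: all influences can vanish, or two distinct
      # edges can deliver opposing nonzero influences
      if (c3 && 0L %in% ci && length(js)) {
        all_zero_ok <- all(vapply(js, function(j) 0L %in% cand[[j]], logical(1)))
        if (!all_zero_ok) {
          can_pos <- vapply(seq_along(js), function(k) (1L * ss[[k]]) %in% cand[[js[[k]]]], logical(1))
          can_neg <- vapply(seq_along(js), function(k) (-1L * ss[[k]]) %in% cand[[js[[k]]]], logical(1))
          pair_ok <- any(can_pos) && any(can_neg) &&
            !(sum(can_pos) == 1L && sum(can_neg) == 1L && which(can_pos) == which(can_neg))
          if (!pair_ok) {
            ci <- setdiff(ci, 0L)
            changed <- TRUE
          }
        }
      }
      if (length(ci) == 0L) return(NULL)
      cand[[i]] <- ci
    }
    if (c4) {
      # possible foundedness: pf[i, v] means node i could take nonzero label v
      # (v in {+1 -> col 1, -1 -> col 2}) on some chain rooted in an input
      pf <- matrix(FALSE, n, 2L)
      for (i in seq_len(n)) {
        if (inst$is_input[[i]]) {
          pf[i, 1L] <- 1L %in% cand[[i]]
          pf[i, 2L] <- -1L %in% cand[[i]]
        }
      }
      repeat {
        grew <- FALSE
        for (i in seq_len(n)) {
          if (inst$is_input[[i]]) next
          js <- inst$pred_j[[i]]
          ss <- inst$pred_s[[i]]
          if (!length(js)) next
          for (col in 1:2) {
            v <- c(1L, -1L)[[col]]
            if (pf[i, col] || !v %in% cand[[i]]) next
            for (k in seq_along(js)) {
              u <- v * ss[[k]] # required predecessor label
              ucol <- if (u == 1L) 1L else 2L
              if (pf[js[[k]], ucol]) { pf[i, col] <- TRUE; grew <- TRUE; break }
            }
          }
        }
        if (!grew) break
      }
      for (i in seq_len(n)) {
        ci <- cand[[i]]
        if (1L %in% ci && !pf[i, 1L]) { ci <- setdiff(ci, 1L); changed <- TRUE }
        if (-1L %in% ci && !pf[i, 2L]) { ci <- setdiff(ci, -1L); changed <- TRUE }
        if (length(ci) == 0L) return(NULL)
        cand[[i]] <- ci
      }
    }
    if (!changed) return(cand)
  }
}

## ---- full constraint check ------------------------------------------------

# violations on an integer labeling vector (by node index); returns a
# data.frame(node, constraint)
violations_int <- function(inst, lab, notion = inst$notion) {
  viol_node <- character()
  viol_con <- character()
  c3 <- notion_has_c3(notion)
  c4 <- notion_has_c4(notion)
  founded <- NULL
  if (c4) founded <- founded_int(inst, lab)
  for (i in seq_len(inst$n)) {
    li <- lab[[i]]
    # C1 handled by caller against the profile (see violations())
    if (!inst$is_input[[i]]) {
      js <- inst$pred_j[[i]]
      ss <- inst$pred_s[[i]]
      infl <- if (length(js)) lab[js] * ss else integer()
      if (li != 0L) {
        if (!any(infl == li)) {
          viol_node <- c(viol_node, inst$nodes[[i]]); viol_con <- c(viol_con, "C2")
        }
      } else if (c3) {
        if (any(infl != 0L) && !(any(infl == 1L) && any(infl == -1L))) {
          viol_node <- c(viol_node, inst$nodes[[i]]); viol_con <- c(viol_con, "C3")
        }
      }
    }
    if (c4 && li != 0L && !founded[[i]]) {
      viol_node <- c(viol_node, inst$nodes[[i]]); viol_con <- c(viol_con, "C4")
    }
  }
  data.frame(node = viol_node, constraint = viol_con, stringsAsFactors = FALSE)
}

# founded set as logical vector over node indices (least fixpoint from inputs)
founded_int <- function(inst, lab) {
  f <- inst$is_input
  repeat {
    grew <- FALSE
    for (i in seq_len(inst$n)) {
      if (f[[i]] || lab[[i]] == 0L) next
      js <- inst$pred_j[[i]]
      ss <- inst$pred_s[[i]]
      if (!length(js)) next
      for (k in seq_along(js)) {
        if (f[[js[[k]]]] && lab[[js[[k]]]] * ss[[k]] == lab[[i]]) {
          f[[i]] <- TRUE; grew <- TRUE; break
        }
      }
    }
    if (!grew) break
  }
  f
}

## ---- public definitional operations --------------------------------------

#' Constraint violations of a total labeling
#'
#' Evaluates the four local/global constraints on a total labeling:
#' C1 (satisfy observations), C2 (a change must be justified by a
#' predecessor's influence), C3 (a no-change must be justified; only under
#' SP/FSP) and C4 (a change must be founded in an input; only under
#' FWP/FSP).  An empty result means the labeling is consistent under the
#' notion.
#'
#' @param graph an [interaction_graph()].
#' @param profile an [experimental_profile()].
#' @param labeling named vector over all graph nodes with values in
#'   `-1, 0, 1` (or tokens `"+", "0", "-"`).
#' @param notion one of `"WP"`, `"SP"`, `"FWP"`, `"FSP"`.
#' @return data.frame with columns `node` and `constraint`.
#' @export
violations <- function(graph, profile, labeling, notion = "FSP") {
  check_notion(notion)
  lab <- as_total_labeling(graph, labeling)
  inst <- build_instance(graph, profile, notion, use_obs = FALSE)
  out <- violations_int(inst, lab[inst$nodes], notion)
  # C1 against the profile
  meas <- intersect(profile$measured, graph$nodes)
  for (m in meas) {
    if (!lab[[m]] %in% allowed_labels(profile$discrete[[m]])) {
      out <- rbind(out, data.frame(node = m, constraint = "C1", stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$node, out$constraint), , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_total_labeling <- function(graph, labeling) {
  if (is.character(labeling)) {
    labeling <- stats::setNames(token_to_node_label(unname(labeling)), names(labeling))
  }
  labeling <- stats::setNames(as.integer(labeling), names(labeling))
  missing <- setdiff(graph$nodes, names(labeling))
  if (length(missing)) {
    stop("labeling is not total; missing node(s): ", paste(missing, collapse = ", "))
  }
  if (!all(labeling %in% c(-1L, 0L, 1L))) stop("labels must be in {-1, 0, 1}")
  labeling[graph$nodes]
}

#' Founded nodes of a labeling
#'
#' Least fixpoint of the foundedness rule: the inputs are founded, and a
#' node with nonzero label is founded if some predecessor edge delivers a
#' matching influence from a founded node.  A changed node satisfies
#' Constraint 4 exactly when it belongs to this set; the rule excludes
#' self-justifying positive feedback loops.
#'
#' @param graph an [interaction_graph()].
#' @param labeling total labeling (named vector, values `-1, 0, 1` or tokens).
#' @param inputs character vector of input node identifiers.
#' @return character vector of founded nodes (always includes the inputs).
#' @export
founded_nodes <- function(graph, labeling, inputs) {
  lab <- as_total_labeling(graph, labeling)
  profile <- experimental_profile(inputs = inputs)
  inst <- build_instance(graph, profile, "FWP", use_obs = FALSE)
  graph$nodes[founded_int(inst, lab[inst$nodes])]
}

## ---- search ---------------------------------------------------------------

# mode "exists": return first solution (integer vector) or NULL
# mode "enumerate": return list of solutions (up to limit + 1, so callers can
#   detect truncation); deterministic lexicographic order unless value_order
#   is supplied (list of per-node integer orderings, used for randomized
#   sampling of a witness labeling)
search_labelings <- function(inst, mode = c("exists", "enumerate"),
                             limit = Inf, value_order = NULL) {
  mode <- match.arg(mode)
  cand0 <- propagate_cand(inst, inst$cand)
  if (is.null(cand0)) {
    return(if (mode == "exists") NULL else list())
  }
  solutions <- list()
  nsol <- 0L
  found_one <- NULL
  n <- inst$n

  dfs <- function(cand, pos) {
    if (!is.null(found_one)) return()
    # advance over already-singleton nodes
    while (pos <= n && length(cand[[pos]]) == 1L) pos <- pos + 1L
    if (pos > n) {
      lab <- vapply(cand, `[[`, integer(1), 1L)
      if (nrow(violations_int(inst, lab)) == 0L) {
        if (mode == "exists") {
          found_one <<- lab
        } else {
          nsol <<- nsol + 1L
          if (nsol <= limit + 1) solutions[[nsol]] <<- lab
        }
      }
      return()
    }
    ord <- if (is.null(value_order)) NODE_LABELS else value_order[[pos]]
    vals <- ord[ord %in% cand[[pos]]]
    for (v in vals) {
      if (!is.null(found_one)) return()
      if (mode == "enumerate" && nsol > limit) return()
      cand2 <- cand
      cand2[[pos]] <- v
      cand2 <- propagate_cand(inst, cand2)
      if (!is.null(cand2)) dfs(cand2, pos + 1L)
    }
  }
  dfs(cand0, 1L)
  if (mode == "exists") found_one else solutions
}

labeling_named <- function(inst, lab) stats::setNames(lab, inst$nodes)

#' Is a graph consistent with a profile under a notion?
#'
#' True when at least one total labeling satisfies all constraints of the
#' notion for all nodes.
#'
#' @inheritParams violations
#' @return logical scalar.
#' @export
is_consistent <- function(graph, profile, notion = "FSP") {
  inst <- build_instance(graph, profile, notion)
  !is.null(search_labelings(inst, "exists"))
}

#' Enumerate all consistent total labelings
#'
#' Yields every consistent labeling exactly once, in lexicographic order
#' over the sorted node identifiers with value order `+ < 0 < -`.  Labeling
#' counts are exponential in the worst case, so enumeration is guarded by a
#' limit.
#'
#' @inheritParams violations
#' @param limit maximum number of labelings to return before raising a
#'   truncation error (default `1e6`).
#' @return list of named integer vectors (values `-1, 0, 1`); empty when
#'   inconsistent.
#' @export
enumerate_labelings <- function(graph, profile, notion = "FSP", limit = 1e6) {
  if (is.null(limit)) limit <- Inf
  if (limit <= 0) stop("limit must be positive")
  inst <- build_instance(graph, profile, notion)
  sols <- search_labelings(inst, "enumerate", limit = limit)
  if (length(sols) > limit) {
    stop(errorCondition(
      sprintf("more than %g consistent labelings; enumeration truncated", limit),
      class = c("sc_limit_error", "error", "condition")
    ))
  }
  lapply(sols, labeling_named, inst = inst)
}

#' Does a consistent labeling extend a partial assignment?
#'
#' Satisfiability query used by the cautious prediction machinery: tests
#' whether some consistent labeling assigns the pinned values.
#'
#' @inheritParams violations
#' @param pinned named vector of node labels (values `-1, 0, 1` or tokens)
#'   to be fixed during the search; empty means plain consistency.
#' @return logical scalar.
#' @export
exists_labeling <- function(graph, profile, notion = "FSP", pinned = NULL) {
  inst <- build_instance(graph, profile, notion, pinned = pinned)
  !is.null(search_labelings(inst, "exists"))
}
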