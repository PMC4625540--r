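#' Confront an interaction graph with an experimental profile
#'
#' The central analysis of the package: checks global sign consistency of a
#' signed network and a discretized steady-state shift profile under the
#' chosen notion, computes the minimal correction sets and inconsistency
#' index when inconsistent, and derives the cautious prediction map (under
#' minimal repair when needed).
#'
#' @param graph an [interaction_graph()].
#' @param profile an [experimental_profile()].
#' @param notion consistency notion, one of `"WP"` (weak propagation: every
#'   change justified by a predecessor), `"SP"` (additionally every
#'   no-change justified), `"FWP"`, `"FSP"` (the founded variants filtering
#'   self-justifying positive feedback loops).  Default `"FSP"`.
#' @param auto_inputs if TRUE (default), predecessor-free nodes are added to
#'   the profile's input set.
#' @param scenfit if TRUE also compute the SCEN-FIT correction count.
#' @param max_repairs cap on the repair cardinality searched.
#' @return an object of class `sc_fit` with components `graph`, `profile`,
#'   `notion`, `consistent`, `mcos` (an `mcos_result`), `scenfit` (or NULL)
#'   and `predictions` (named character map over non-artificial nodes).
#' @examples
#' g <- interaction_graph(data.frame(source = "A", target = "B", sign = "+"))
#' p <- experimental_profile(c(A = "+"), inputs = "A")
#' fit <- confront(g, p, notion = "FSP")
#' predict(fit)
#' @export
confront <- function(graph, profile, notion = "FSP", auto_inputs = TRUE,
                     scenfit = FALSE, max_repairs = 32L) {
  check_notion(notion)
  profile <- reconcile(graph, profile)
  if (auto_inputs) {
    profile$inputs <- sort(union(profile$inputs, signcon::auto_inputs(graph)))
  }
  m <- mcos(graph, profile, notion, max_size = max_repairs)
  preds <- predict_under_mcos(graph, profile, notion, max_size = max_repairs)
  sf <- if (scenfit) signcon::scenfit(graph, profile, notion) else NULL
  structure(
    list(
      graph = graph, profile = profile, notion = notion,
      consistent = m$size == 0L, mcos = m, scenfit = sf,
      predictions = preds, call = match.call()
    ),
    class = "sc_fit"
  )
}

#' @export
print.sc_fit <- function(x, ...) {
  cat(sprintf(
    "Sign consistency fit (%s): %s\n", x$notion,
    if (x$consistent) "consistent" else sprintf(
      "inconsistent; %d correction(s) in %d minimal set(s), index %.4g",
      x$mcos$size, length(x$mcos$sets), x$mcos$index
    )
  ))
  tab <- table(factor(x$predictions, levels = PRED_LABELS))
  cat("  predictions:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.sc_fit <- function(object, ...) {
  unmeasured <- setdiff(names(object$predictions), object$profile$measured)
  counts <- prediction_counts(object$predictions, unmeasured)
  out <- list(
    notion = object$notion,
    consistent = object$consistent,
    mcos_size = object$mcos$size,
    n_mcos_sets = length(object$mcos$sets),
    inconsistency_index = object$mcos$index,
    scenfit_corrections = if (is.null(object$scenfit)) NA_integer_ else object$scenfit$corrections,
    n_nodes = length(object$graph$nodes) - length(object$graph$artificial),
    n_measured = length(object$profile$measured),
    n_inputs = length(object$profile$inputs),
    counts = counts,
    recovery = if (counts$n > 0L) recovery_rate(object$predictions, unmeasured) else NA_real_,
    information_gain = if (counts$n > 0L) information_gain(counts) else NA_real_
  )
  class(out) <- "summary.sc_fit"
  out
}

#' @export
print.summary.sc_fit <- function(x, ...) {
  cat(sprintf("Sign consistency fit under %s\n", x$notion))
  cat(sprintf("  nodes: %d  measured: %d  inputs: %d\n", x$n_nodes, x$n_measured, x$n_inputs))
  cat(sprintf("  consistent: %s", x$consistent))
  if (!x$consistent) {
    cat(sprintf("  (MCoS size %d in %d sets, inconsistency index %.4g)",
                x$mcos_size, x$n_mcos_sets, x$inconsistency_index))
  }
  cat("\n")
  if (!is.na(x$scenfit_corrections)) {
    cat(sprintf("  SCEN-FIT corrections: %d\n", x$scenfit_corrections))
  }
  if (x$counts$n > 0L) {
    cat(sprintf(
      "  unmeasured nodes: %d  strong: %d  weak: %d  none: %d\n",
      x$counts$n, x$counts$k, x$counts$l, x$counts$m
    ))
    cat(sprintf("  recovery rate: %.3f  information gain: %.3f\n",
                x$recovery, x$information_gain))
  }
  invisible(x)
}

#' @export
predict.sc_fit <- function(object, ...) {
  object$predictions
}

#' Plot a sign consistency fit
#'
#' Draws the interaction graph with nodes colored by their prediction
#' (green increase, red decrease, blue no-change, pale variants for weak
#' predictions, grey for none).  Requires the igraph package.
#'
#' @param x an `sc_fit` object.
#' @param ... passed to `igraph::plot.igraph`.
#' @export
plot.sc_fit <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("plotting requires the igraph package")
  }
  keep <- setdiff(x$graph$nodes, x$graph$artificial)
  e <- x$graph$edges
  e <- e[e$source %in% keep & e$target %in% keep, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(
    data.frame(from = e$source, to = e$target),
    directed = TRUE, vertices = keep
  )
  cols <- c(`+` = "#2ca02c", `-` = "#d62728", `0` = "#1f77b4",
            `w+` = "#98df8a", `w-` = "#ff9896", `chg` = "#c5b0d5", `no` = "grey80")
  igraph::V(ig)$color <- cols[x$predictions[keep]]
  igraph::E(ig)$lty <- ifelse(e$sign > 0L, 1, 2)
  igraph::plot.igraph(ig, ...)
  invisible(x)
}
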