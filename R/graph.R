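#' Construct an interaction graph
#'
#' An interaction graph is a signed directed graph: a set of node identifiers
#' and a set of edges, each labeled `+` (the source tends to increase the
#' target) or `-` (tends to decrease it).  Unsigned interactions are encoded
#' as two parallel edges of opposite sign.  Self-loops are permitted.
#' Duplicate edges (same source, target and sign) are collapsed.
#'
#' @param edges a data.frame with columns `source`, `target`, `sign`
#'   (`"+"`/`"-"` or `+1`/`-1`), or NULL for an edgeless graph.
#' @param nodes character vector of node identifiers; defaults to all edge
#'   endpoints.  Extra isolated nodes may be listed here.
#' @return an object of class `interaction_graph` with components `nodes`
#'   (sorted character vector), `edges` (data.frame `source`, `target`,
#'   `sign` with integer signs) and `artificial` (names of artificial repair
#'   nodes, empty for user-built graphs).
#' @examples
#' g <- interaction_graph(data.frame(source = "A", target = "B", sign = "+"))
#' @export
interaction_graph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(), sign = integer())
  }
  if (!is.data.frame(edges) || !all(c("source", "target", "sign") %in% names(edges))) {
    stop("edges must be a data.frame with columns source, target, sign")
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (is.character(edges$sign) || is.factor(edges$sign)) {
    s <- c(`+` = 1L, `-` = -1L)[as.character(edges$sign)]
    if (anyNA(s)) stop("edge signs must be '+' or '-'")
    edges$sign <- unname(s)
  }
  edges$sign <- as.integer(edges$sign)
  if (nrow(edges) && !all(edges$sign %in% c(1L, -1L))) stop("edge signs must be +1 or -1")

  nodes <- sort(unique(c(as.character(nodes), edges$source, edges$target)))
  if (length(nodes) == 0L) stop("graph must have at least one node")
  bad <- nodes[nodes == "" | grepl("[\t\n]", nodes)]
  if (length(bad)) stop("invalid node identifiers (empty or containing tab/newline)")

  # collapse exact duplicates, keep opposite-sign parallels
  if (nrow(edges)) {
    key <- paste(edges$source, edges$target, edges$sign, sep = "\r")
    edges <- edges[!duplicated(key), c("source", "target", "sign")]
    ord <- order(edges$source, edges$target, -edges$sign)
    edges <- edges[ord, , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(
    list(nodes = nodes, edges = edges, artificial = character()),
    class = "interaction_graph"
  )
}

#' @export
print.interaction_graph <- function(x, ...) {
  n_art <- length(x$artificial)
  cat(sprintf(
    "Interaction graph: %d nodes, %d signed edges%s\n",
    length(x$nodes), nrow(x$edges),
    if (n_art) sprintf(" (%d artificial repair nodes)", n_art) else ""
  ))
  if (nrow(x$edges)) {
    show <- utils::head(x$edges, 10L)
    cat(paste0(
      "  ", show$source, " -", ifelse(show$sign > 0L, "+", "-"), "> ", show$target,
      collapse = "\n"
    ), "\n")
    if (nrow(x$edges) > 10L) cat(sprintf("  ... and %d more edges\n", nrow(x$edges) - 10L))
  }
  invisible(x)
}

#' Nodes without predecessors
#'
#' Returns the nodes with no incoming edge.  In steady-state shift
#' experiments where the perturbed species are unknown, these are
#' conventionally taken as the input nodes (their change needs no upstream
#' justification).
#'
#' @param graph an [interaction_graph()].
#' @return character vector of predecessor-free node identifiers.
#' @export
auto_inputs <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  setdiff(graph$nodes, unique(graph$edges$target))
}

#' Reconcile a profile with a graph
#'
#' Observations (and inputs) referring to nodes absent from the graph are
#' dropped with a warning reporting the count; real datasets typically cover
#' only part of a curated network.  Node matching is exact and
#' case-sensitive.
#'
#' @param graph an [interaction_graph()].
#' @param profile an [experimental_profile()].
#' @return the profile restricted to graph nodes.
#' @export
reconcile <- function(graph, profile) {
  stopifnot(inherits(graph, "interaction_graph"), inherits(profile, "experimental_profile"))
  drop_m <- setdiff(profile$measured, graph$nodes)
  drop_i <- setdiff(profile$inputs, graph$nodes)
  if (length(drop_m)) {
    warning(sprintf("dropped %d observation(s) for nodes absent from the graph", length(drop_m)))
    profile$measured <- setdiff(profile$measured, drop_m)
    profile$discrete <- profile$discrete[profile$measured]
    if (!is.null(profile$raw)) profile$raw <- profile$raw[profile$measured]
  }
  if (length(drop_i)) {
    warning(sprintf("dropped %d input(s) absent from the graph", length(drop_i)))
    profile$inputs <- setdiff(profile$inputs, drop_i)
  }
  profile
}
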