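## Synthetic instance generation.
##
## Emulates a steady-state shift experiment on a random signed network: a
## hidden total labeling consistent under the chosen notion plays the role
## of the true system response, of which a fraction is observed, optionally
## softened to uncertain labels or corrupted by sign flips.  Because the
## hidden labeling is drawn through the consistency engine itself (with
## randomized branching), it is valid under any notion including FSP, where
## plain forward propagation could not guarantee justified no-changes.

#' Configuration for the synthetic instance generator
#'
#' @param n_nodes number of nodes (>= 1).
#' @param n_edges number of distinct (source, target) pairs (self-loops
#'   allowed); at most `n_nodes^2`.
#' @param p_negative probability that an edge is inhibitory.
#' @param p_input probability that a node with predecessors is additionally
#'   declared an input (predecessor-free nodes are always inputs).
#' @param frac_observed fraction of nodes measured.
#' @param frac_uncertain probability that an observed change is softened to
#'   the matching uncertain label (`+` to `"u+"`, `-` to `"u-"`; no-change
#'   observations are not softened).
#' @param noise_flips probability that an observation is flipped to a
#'   uniformly chosen different certain label.
#' @param notion consistency notion the hidden labeling satisfies.
#' @param seed integer seed; fixes all randomness.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_nodes = 12L, n_edges = 18L, p_negative = 0.3,
                         p_input = 0.05, frac_observed = 0.5,
                         frac_uncertain = 0.1, noise_flips = 0,
                         notion = "FSP", seed = 1L) {
  check_notion(notion)
  stopifnot(n_nodes >= 1L, n_edges >= 0L)
  if (n_edges > n_nodes^2) stop("n_edges exceeds the number of distinct (source, target) pairs")
  fracs <- c(p_negative, p_input, frac_observed, frac_uncertain, noise_flips)
  if (any(fracs < 0 | fracs > 1)) stop("probabilities must lie in [0, 1]")
  structure(
    list(
      n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
      p_negative = p_negative, p_input = p_input,
      frac_observed = frac_observed, frac_uncertain = frac_uncertain,
      noise_flips = noise_flips, notion = notion, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Random signed directed graph
#'
#' Draws `n_edges` distinct (source, target) pairs uniformly (self-loops
#' allowed), each negative with probability `p_negative`.  Deterministic
#' under the config seed.
#'
#' @param cfg a [synth_config()].
#' @return an [interaction_graph()].
#' @export
random_graph <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  rng <- make_rng(derive_seed(cfg$seed, 1L))
  nodes <- sprintf("n%03d", seq_len(cfg$n_nodes))
  if (cfg$n_edges == 0L) return(interaction_graph(nodes = nodes))
  pair_ids <- rng$sample(seq_len(cfg$n_nodes^2), cfg$n_edges)
  src <- ((pair_ids - 1L) %/% cfg$n_nodes) + 1L
  tgt <- ((pair_ids - 1L) %% cfg$n_nodes) + 1L
  signs <- ifelse(rng$runif(cfg$n_edges) < cfg$p_negative, -1L, 1L)
  interaction_graph(
    data.frame(source = nodes[src], target = nodes[tgt], sign = signs),
    nodes = nodes
  )
}

#' Sample a full synthetic instance with a known hidden labeling
#'
#' Generates a random graph, marks predecessor-free nodes (plus extra nodes
#' with probability `p_input`) as inputs, draws a hidden total labeling
#' consistent under `cfg$notion` by randomized consistency search, and
#' builds an experimental profile observing `ceiling(frac_observed * n)`
#' nodes: each reports the hidden label, softened or flipped as configured.
#' With `noise_flips = 0` the hidden labeling witnesses consistency of the
#' generated instance.
#'
#' @param cfg a [synth_config()].
#' @return list with components `graph`, `hidden` (named integer labeling)
#'   and `profile`.
#' @export
sample_instance <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  graph <- random_graph(cfg)
  rng <- make_rng(derive_seed(cfg$seed, 2L))

  inputs <- auto_inputs(graph)
  others <- setdiff(graph$nodes, inputs)
  if (length(others) && cfg$p_input > 0) {
    extra <- others[rng$runif(length(others)) < cfg$p_input]
    inputs <- sort(c(inputs, extra))
  }
  blank <- experimental_profile(inputs = inputs)

  hidden <- NULL
  for (try in 1:5) {
    inst <- build_instance(graph, blank, cfg$notion)
    value_order <- lapply(seq_len(inst$n), function(i) {
      make_rng(derive_seed(cfg$seed, 100L + 7L * try + i))$shuffle(NODE_LABELS)
    })
    sol <- search_labelings(inst, "exists", value_order = value_order)
    if (!is.null(sol)) {
      hidden <- labeling_named(inst, sol)
      break
    }
  }
  if (is.null(hidden)) stop("no consistent labeling found for the sampled graph") # unreachable guard

  n_obs <- ceiling(cfg$frac_observed * length(graph$nodes))
  observed <- sort(rng$sample(graph$nodes, n_obs))
  tok <- node_label_token(hidden[observed])
  if (cfg$frac_uncertain > 0) {
    soften <- rng$runif(length(tok)) < cfg$frac_uncertain & tok %in% c("+", "-")
    tok[soften] <- paste0("u", tok[soften])
  }
  if (cfg$noise_flips > 0) {
    flip <- rng$runif(length(tok)) < cfg$noise_flips
    for (i in which(flip)) {
      certain <- c("+", "0", "-")
      base <- if (tok[[i]] %in% c("u+", "u-")) substring(tok[[i]], 2L) else tok[[i]]
      alt <- setdiff(certain, base)
      tok[[i]] <- alt[[rng$int(1L, length(alt))]]
    }
  }
  profile <- experimental_profile(
    discrete = stats::setNames(tok, observed), inputs = inputs
  )
  list(graph = graph, hidden = hidden, profile = profile)
}

#' Built-in demonstration fixtures
#'
#' Small named instances used throughout the documentation and tests:
#' \describe{
#'   \item{chain}{one positive edge A -> B, input A, both observed up;
#'     consistent under all notions.}
#'   \item{inconsistent_pair}{two nodes activating/inhibiting each other in
#'     a negative loop with no inputs; locally consistent for each node but
#'     globally inconsistent.}
#'   \item{positive_loop}{a chain feeding a two-node positive feedback loop
#'     (B <-> C) and a downstream reporter D; with the input unchanged and D
#'     up, the loop must self-justify, so the instance is SP-consistent but
#'     not founded (FWP/FSP-inconsistent).}
#'   \item{fork}{one input C activating both A and B, observed to move in
#'     opposite directions; inconsistent, with two singleton correction
#'     sets.}
#'   \item{feedback}{an eight-node network with a positive feedback loop
#'     (E <-> F), opposing influences on G and a measured unchanged
#'     reporter H; inputs A and D increased.  Illustrates how the four
#'     notions nest and sharpen predictions.}
#' }
#'
#' @return named list; each element is a list with `graph` and `profile`.
#' @export
toy_fixtures <- function() {
  list(
    chain = list(
      graph = interaction_graph(data.frame(source = "A", target = "B", sign = "+")),
      profile = experimental_profile(c(A = "+", B = "+"), inputs = "A")
    ),
    inconsistent_pair = list(
      graph = interaction_graph(data.frame(
        source = c("B", "A"), target = c("A", "B"), sign = c("+", "-")
      )),
      profile = experimental_profile(c(A = "+", B = "+"))
    ),
    positive_loop = list(
      graph = interaction_graph(data.frame(
        source = c("A", "B", "C", "C"),
        target = c("B", "C", "B", "D"),
        sign = c("+", "+", "+", "+")
      )),
      profile = experimental_profile(c(A = "0", D = "+"), inputs = "A")
    ),
    fork = list(
      graph = interaction_graph(data.frame(
        source = c("C", "C"), target = c("A", "B"), sign = c("+", "+")
      )),
      profile = experimental_profile(c(A = "+", B = "-"), inputs = "C")
    ),
    feedback = list(
      graph = interaction_graph(data.frame(
        source = c("A", "A", "D", "D", "E", "F", "E", "F", "G", "G"),
        target = c("B", "G", "G", "E", "F", "E", "C", "C", "C", "H"),
        sign = c("+", "+", "-", "+", "+", "+", "+", "+", "+", "+")
      )),
      profile = experimental_profile(c(A = "+", D = "+", H = "0"), inputs = c("A", "D"))
    )
  )
}
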