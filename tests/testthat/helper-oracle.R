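# Independent brute-force oracle: enumerates all 3^|V| total labelings as a
# matrix and filters by the constraint definitions directly (vectorized over
# rows).  Shares no code with the package's search engine.

brute_labelings <- function(graph, profile, notion) {
  nodes <- graph$nodes
  n <- length(nodes)
  L <- as.matrix(expand.grid(rep(list(c(1L, 0L, -1L)), n), KEEP.OUT.ATTRS = FALSE))
  colnames(L) <- nodes
  storage.mode(L) <- "integer"
  ok <- rep(TRUE, nrow(L))

  for (m in intersect(profile$measured, nodes)) {
    ok <- ok & L[, m] %in% allowed_labels(profile$discrete[[m]])
  }
  e <- graph$edges
  for (i in nodes) {
    if (i %in% profile$inputs) next
    sel <- e$target == i
    li <- L[, i]
    if (any(sel)) {
      js <- e$source[sel]
      ss <- e$sign[sel]
      INF <- L[, js, drop = FALSE] * rep(ss, each = nrow(L))
      matchv <- rowSums(INF == li) > 0
      haspos <- rowSums(INF == 1L) > 0
      hasneg <- rowSums(INF == -1L) > 0
      anynz <- rowSums(INF != 0L) > 0
    } else {
      matchv <- haspos <- hasneg <- anynz <- rep(FALSE, nrow(L))
    }
    ok <- ok & (li == 0L | matchv) # C2
    if (notion %in% c("SP", "FSP")) {
      ok <- ok & (li != 0L | !anynz | (haspos & hasneg)) # C3
    }
  }
  if (notion %in% c("FWP", "FSP")) {
    idx <- which(ok)
    if (length(idx)) {
      Ls <- L[idx, , drop = FALSE]
      FND <- matrix(rep(nodes %in% profile$inputs, each = length(idx)),
                    nrow = length(idx), dimnames = list(NULL, nodes))
      repeat {
        F0 <- FND
        if (nrow(e)) {
          for (k in seq_len(nrow(e))) {
            j <- e$source[[k]]; i <- e$target[[k]]; s <- e$sign[[k]]
            FND[, i] <- FND[, i] | (FND[, j] & Ls[, i] != 0L & Ls[, j] * s == Ls[, i])
          }
        }
        if (identical(FND, F0)) break
      }
      viol <- rowSums(Ls != 0L & !FND) > 0
      ok[idx[viol]] <- FALSE
    }
  }
  L[ok, , drop = FALSE]
}

brute_consistent <- function(graph, profile, notion) {
  nrow(brute_labelings(graph, profile, notion)) > 0L
}

brute_prediction_map <- function(graph, profile, notion) {
  L <- brute_labelings(graph, profile, notion)
  stopifnot(nrow(L) > 0L)
  vapply(colnames(L), function(nm) classify(unique(L[, nm])), character(1))
}

# independent minimum-correction search: manual artificial-input construction,
# exhaustive over repair subsets of size 0..max_k, brute-force feasibility
brute_mcos_size <- function(graph, profile, notion, max_k = 2L) {
  if (brute_consistent(graph, profile, notion)) {
    return(list(size = 0L, sets = list(data.frame(node = character(), sign = integer()))))
  }
  targets <- sort(setdiff(graph$nodes, profile$inputs))
  cand <- data.frame(node = rep(targets, each = 2L),
                     sign = rep(c(1L, -1L), length(targets)))
  for (k in seq_len(min(max_k, nrow(cand)))) {
    hits <- list()
    combos <- utils::combn(nrow(cand), k)
    for (ci in seq_len(ncol(combos))) {
      r <- cand[combos[, ci], , drop = FALSE]
      art <- paste0("zz_art", seq_len(k)) # sorts after user nodes; never clashes
      g2 <- interaction_graph(
        rbind(graph$edges, data.frame(source = art, target = r$node, sign = r$sign)),
        nodes = c(graph$nodes, art)
      )
      p2 <- experimental_profile(
        discrete = c(profile$discrete, stats::setNames(rep("+", k), art)),
        inputs = c(profile$inputs, art)
      )
      if (brute_consistent(g2, p2, notion)) {
        rownames(r) <- NULL
        hits[[length(hits) + 1L]] <- r
      }
    }
    if (length(hits)) return(list(size = k, sets = hits))
  }
  list(size = NA_integer_, sets = list())
}

# random small test instance with a seeded mix of notions, uncertain
# observations and input choices
random_test_instance <- function(seed, n_max = 8L) {
  set.seed(seed)
  n <- sample(2:n_max, 1L)
  nodes <- sprintf("v%02d", seq_len(n))
  n_edges <- sample(0:(2L * n), 1L)
  edges <- if (n_edges > 0L) {
    data.frame(
      source = sample(nodes, n_edges, replace = TRUE),
      target = sample(nodes, n_edges, replace = TRUE),
      sign = sample(c(1L, -1L), n_edges, replace = TRUE)
    )
  } else NULL
  graph <- interaction_graph(edges, nodes = nodes)
  inputs <- auto_inputs(graph)
  extra <- setdiff(nodes, inputs)
  if (length(extra) && runif(1) < 0.3) {
    inputs <- c(inputs, sample(extra, 1L))
  }
  n_obs <- sample(1:n, 1L)
  observed <- sample(nodes, n_obs)
  labels <- sample(c("-", "u-", "0", "u+", "+"), n_obs, replace = TRUE)
  profile <- experimental_profile(stats::setNames(labels, observed), inputs = inputs)
  notion <- sample(c("WP", "SP", "FWP", "FSP"), 1L)
  list(graph = graph, profile = profile, notion = notion)
}

labeling_key <- function(lab) {
  paste(c(`1` = "a", `0` = "b", `-1` = "c")[as.character(lab)], collapse = "")
}
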