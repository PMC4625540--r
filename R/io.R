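## Plain-text formats.
##
## Networks: one edge per line, "source<TAB>sign<TAB>target" with sign in
## {+, -, ?}; "?" expands to two parallel edges of opposite sign.  Profiles:
## one node per line, "node<TAB>value" where value is a real (discretized),
## an observation token (+, -, 0, u+, u-) or the word "input".  Lines
## starting with "#" and blank lines are ignored.  The dialects are strict:
## malformed lines raise classed parse errors naming the line.

parse_error <- function(path, lineno, msg) {
  stop(errorCondition(
    sprintf("%s: line %d: %s", path, lineno, msg),
    class = c("sc_parse_error", "error", "condition")
  ))
}

content_lines <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(paste0("file not found: ", path),
                        class = c("sc_parse_error", "error", "condition")))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a signed network from a tab-separated edge file
#'
#' @param path file with lines `source<TAB>sign<TAB>target`, sign one of
#'   `+`, `-`, `?` (unsigned: expanded to two parallel edges of opposite
#'   sign).  `#`-comments and blank lines are ignored.
#' @return an [interaction_graph()] whose node set is all edge endpoints.
#' @export
read_network <- function(path) {
  cl <- content_lines(path)
  if (length(cl$lines) == 0L) stop("empty network file: ", path)
  parts <- strsplit(cl$lines, "\t", fixed = TRUE)
  src <- character(0); tgt <- character(0); sgn <- integer(0)
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (length(p) != 3L || any(p == "")) {
      parse_error(path, cl$lineno[[k]], "expected 'source<TAB>sign<TAB>target'")
    }
    if (!p[[2]] %in% c("+", "-", "?")) {
      parse_error(path, cl$lineno[[k]], paste0("unknown sign token '", p[[2]], "'"))
    }
    if (p[[2]] == "?") {
      src <- c(src, p[[1]], p[[1]]); tgt <- c(tgt, p[[3]], p[[3]]); sgn <- c(sgn, 1L, -1L)
    } else {
      src <- c(src, p[[1]]); tgt <- c(tgt, p[[3]])
      sgn <- c(sgn, if (p[[2]] == "+") 1L else -1L)
    }
  }
  interaction_graph(data.frame(source = src, target = tgt, sign = sgn))
}

#' Write a signed network
#'
#' Inverse of [read_network()] up to representation: unsigned pairs are
#' written as two signed lines.  Edges are written in the graph's canonical
#' order, so output is byte-stable.
#'
#' @param graph an [interaction_graph()].
#' @param path output file.
#' @export
write_network <- function(graph, path) {
  stopifnot(inherits(graph, "interaction_graph"))
  e <- graph$edges
  writeLines(sprintf("%s\t%s\t%s", e$source, ifelse(e$sign > 0L, "+", "-"), e$target), path)
  invisible(path)
}

#' Read an experimental profile from a tab-separated observation file
#'
#' @param path file with lines `node<TAB>value`; value is a real number
#'   (discretized via `thresholds`), an observation token (`+`, `-`, `0`,
#'   `u+`, `u-`) or the word `input` (marks the node as an input without a
#'   measurement).  A file may use reals or tokens, not both; duplicate
#'   node lines are an error.
#' @param thresholds a [discretization_thresholds()] for real-valued files.
#' @return an [experimental_profile()].
#' @export
read_observations <- function(path, thresholds = default_thresholds()) {
  cl <- content_lines(path)
  if (length(cl$lines) == 0L) stop("empty observation file: ", path)
  parts <- strsplit(cl$lines, "\t", fixed = TRUE)
  nodes <- character(0); values <- character(0); linenos <- integer(0)
  inputs <- character(0)
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (length(p) != 2L || any(p == "")) {
      parse_error(path, cl$lineno[[k]], "expected 'node<TAB>value'")
    }
    if (p[[2]] == "input") {
      inputs <- c(inputs, p[[1]])
    } else {
      nodes <- c(nodes, p[[1]]); values <- c(values, p[[2]]); linenos <- c(linenos, cl$lineno[[k]])
    }
  }
  dup <- nodes[duplicated(nodes)]
  if (length(dup)) {
    parse_error(path, linenos[[which(duplicated(nodes))[1L]]],
                paste0("duplicate observation for node '", dup[[1]], "'"))
  }
  is_token <- values %in% OBS_LABELS
  num <- suppressWarnings(as.numeric(values))
  is_real <- !is.na(num) & !is_token  # "0" parses as numeric but is a token
  bad <- which(!is_token & !is_real)
  if (length(bad)) {
    parse_error(path, linenos[[bad[[1]]]], paste0("bad observation value '", values[[bad[[1]]]], "'"))
  }
  if (any(is_token) && any(is_real)) {
    parse_error(path, linenos[[which(is_real)[1L]]],
                "file mixes real-valued and token observations")
  }
  if (length(nodes) == 0L) {
    return(experimental_profile(inputs = inputs))
  }
  if (any(is_real)) {
    experimental_profile(raw = stats::setNames(num, nodes), inputs = inputs,
                         thresholds = thresholds)
  } else {
    experimental_profile(discrete = stats::setNames(values, nodes), inputs = inputs)
  }
}

#' Write an experimental profile
#'
#' Writes discrete observation tokens (one `node<TAB>token` line per
#' measured node, sorted) followed by `node<TAB>input` lines for the
#' inputs.  Round-trips through [read_observations()] (raw values, if any,
#' are not preserved; the discrete labels are).
#'
#' @param profile an [experimental_profile()].
#' @param path output file.
#' @export
write_observations <- function(profile, path) {
  stopifnot(inherits(profile, "experimental_profile"))
  lines <- c(
    sprintf("%s\t%s", profile$measured, profile$discrete[profile$measured]),
    sprintf("%s\tinput", profile$inputs)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a machine-readable analysis report
#'
#' Serializes a confrontation result as JSON (schema 1) and, optionally,
#' the prediction map as a sorted two-column TSV using the tokens
#' `+ - 0 w+ w- chg no`.  Output is byte-stable for fixed inputs and seed.
#'
#' @param fit an `sc_fit` object from [confront()].
#' @param path_json JSON output path (or NULL to skip).
#' @param path_tsv TSV output path for predictions (or NULL to skip).
#' @param seed seed to record in the report.
#' @return invisibly, the report list.
#' @export
write_report <- function(fit, path_json = NULL, path_tsv = NULL, seed = NA_integer_) {
  stopifnot(inherits(fit, "sc_fit"))
  preds <- fit$predictions[order(names(fit$predictions))]
  report <- list(
    schema = 1L,
    notion = fit$notion,
    consistent = fit$consistent,
    mcos_size = fit$mcos$size,
    mcos_sets = lapply(fit$mcos$sets, function(s) {
      if (nrow(s) == 0L) list() else
        lapply(seq_len(nrow(s)), function(i) list(node = s$node[[i]],
                                                  sign = if (s$sign[[i]] > 0L) "+" else "-"))
    }),
    inconsistency_index = fit$mcos$index,
    scenfit = if (is.null(fit$scenfit)) NULL else fit$scenfit$corrections,
    predictions = as.list(preds),
    metrics = {
      unmeasured <- setdiff(names(fit$predictions), fit$profile$measured)
      if (length(unmeasured)) {
        counts <- prediction_counts(fit$predictions, unmeasured)
        list(n_unmeasured = counts$n, strong = counts$k, weak = counts$l, none = counts$m,
             recovery = recovery_rate(fit$predictions, unmeasured),
             information_gain = information_gain(counts))
      } else list()
    },
    seed = seed,
    versions = list(signcon = as.character(utils::packageVersion("signcon")))
  )
  if (!is.null(path_json)) {
    jsonlite::write_json(report, path_json, auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(path_tsv)) {
    writeLines(sprintf("%s\t%s", names(preds), preds), path_tsv)
  }
  invisible(report)
}
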