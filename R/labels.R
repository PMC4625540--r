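## Label alphabets shared across the package.
##
## Node labels (one admissible behavior per node) are stored internally as
## integers: +1 increase, 0 no-change, -1 decrease.  Observation labels use
## the five-valued alphabet "-", "u-", "0", "u+", "+" where "u-"/"u+" are the
## uncertain decrease/increase bands of the discretization.  Prediction
## labels add the weak classes "w+", "w-", "chg" and the no-prediction class
## "no".

#' @keywords internal
OBS_LABELS <- c("-", "u-", "0", "u+", "+")

#' @keywords internal
PRED_LABELS <- c("+", "-", "0", "w+", "w-", "chg", "no")

NODE_LABELS <- c(1L, 0L, -1L) # canonical value order: + < 0 < -

node_label_token <- function(v) c(`1` = "+", `0` = "0", `-1` = "-")[as.character(v)]

token_to_node_label <- function(tok) {
  map <- c(`+` = 1L, `0` = 0L, `-` = -1L)
  out <- map[tok]
  if (anyNA(out)) stop("invalid node label token: ", paste(tok[is.na(out)], collapse = ", "))
  unname(out)
}

check_obs_label <- function(o) {
  bad <- setdiff(unique(o), OBS_LABELS)
  if (length(bad)) stop("invalid observation label(s): ", paste(bad, collapse = ", "))
  invisible(o)
}

#' Influence of a predecessor on a node
#'
#' The influence of node `source` on its successor along an edge of sign
#' `sign` is the product of the source's label and the edge sign, with the
#' usual sign arithmetic (`0` absorbs).
#'
#' @param labeling named integer vector over graph nodes with values in
#'   `-1, 0, 1` (a total labeling).
#' @param source node identifier of the edge source.
#' @param sign edge sign, `+1`/`-1` or `"+"`/`"-"`.
#' @return the influence as an integer in `-1, 0, 1`.
#' @examples
#' influence(c(j = 1L, i = 0L), "j", -1)
#' @export
influence <- function(labeling, source, sign) {
  if (!source %in% names(labeling)) {
    stop("unknown source node: ", source)
  }
  if (is.character(sign)) sign <- unname(c(`+` = 1L, `-` = -1L)[sign])
  if (!sign %in% c(1L, -1L)) stop("edge sign must be +1 or -1")
  as.integer(labeling[[source]] * sign)
}

#' Node labels admitted by an observation
#'
#' A certain observation pins a node to one label; an uncertain observation
#' (`"u+"`, `"u-"`) admits the corresponding change and no-change.
#'
#' @param obs an observation label, one of `"-", "u-", "0", "u+", "+"`.
#' @return integer vector of admitted node labels (subset of `1, 0, -1`).
#' @export
allowed_labels <- function(obs) {
  check_obs_label(obs)
  switch(obs,
    "+"  = 1L,
    "u+" = c(1L, 0L),
    "0"  = 0L,
    "u-" = c(-1L, 0L),
    "-"  = -1L
  )
}

#' Classify a set of realized node labels into a prediction label
#'
#' Maps the set of labels a node takes across all consistent labelings to
#' the seven-valued prediction alphabet: singletons give strong predictions,
#' two-element sets give the weak predictions `"w+"` (never decreases),
#' `"w-"` (never increases) and `"chg"` (always changes), and the full set
#' gives `"no"`.
#'
#' @param realized integer vector (subset of `1, 0, -1`) or character vector
#'   of tokens `"+", "0", "-"`; must be non-empty.
#' @return a prediction label, one of `"+", "-", "0", "w+", "w-", "chg", "no"`.
#' @examples
#' classify(c(1L, 0L)) # "w+"
#' @export
classify <- function(realized) {
  if (is.character(realized)) realized <- token_to_node_label(realized)
  realized <- unique(as.integer(realized))
  if (length(realized) == 0L) stop("empty realized label set: no admissible behavior")
  if (!all(realized %in% c(1L, 0L, -1L))) stop("realized labels must be in {-1, 0, 1}")
  key <- paste(sort(realized), collapse = ",")
  switch(key,
    "1" = "+", "-1" = "-", "0" = "0",
    "0,1" = "w+", "-1,0" = "w-", "-1,1" = "chg",
    "-1,0,1" = "no"
  )
}
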