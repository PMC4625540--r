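#' Discretization thresholds
#'
#' Four condition-dependent thresholds t1 <= t2 < 0 < t3 <= t4 partition the
#' real line into five bands: certain decrease, uncertain decrease, certain
#' no-change, uncertain increase, certain increase.  The uncertain bands make
#' the discretization robust to borderline log-ratios.  Degenerate thresholds
#' (t1 = t2 or t3 = t4) are legal and make the corresponding uncertain band
#' empty.
#'
#' @param t1,t2,t3,t4 real thresholds with t1 <= t2 < 0 < t3 <= t4.
#' @return a named numeric vector of class `discretization_thresholds`.
#' @export
discretization_thresholds <- function(t1, t2, t3, t4) {
  th <- c(t1 = t1, t2 = t2, t3 = t3, t4 = t4)
  if (anyNA(th) || any(!is.finite(th))) stop("thresholds must be finite")
  if (!(t1 <= t2 && t2 < 0 && 0 < t3 && t3 <= t4)) {
    stop("thresholds must satisfy t1 <= t2 < 0 < t3 <= t4")
  }
  structure(th, class = "discretization_thresholds")
}

#' Default discretization thresholds
#'
#' The typical thresholds for microarray log-ratios: changes beyond +/-2 are
#' certain, changes within +/-0.01 are certain no-change, and the bands in
#' between are uncertain.
#'
#' @return a `discretization_thresholds` object (-2, -0.01, 0.01, 2).
#' @export
default_thresholds <- function() {
  discretization_thresholds(-2, -0.01, 0.01, 2)
}

#' Discretize a measurement into the five-valued observation alphabet
#'
#' Maps a real-valued change (for instance a log-ratio between two steady
#' states) to one of "-", "u-", "0", "u+", "+".  Boundary conventions:
#' x <= t1 is "-", t1 < x <= t2 is "u-", t2 < x < t3 is "0", t3 <= x < t4 is
#' "u+", and t4 <= x is "+".
#'
#' @param x numeric vector of measured changes (finite).
#' @param thresholds a [discretization_thresholds()] object.
#' @return character vector of observation labels, same length as `x`.
#' @examples
#' discretize_value(c(-3, -1, 0, 0.01, 2), default_thresholds())
#' @export
discretize_value <- function(x, thresholds = default_thresholds()) {
  if (!inherits(thresholds, "discretization_thresholds")) {
    thresholds <- do.call(discretization_thresholds, as.list(unname(thresholds)))
  }
  if (length(x) == 0L) stop("no values to discretize")
  if (anyNA(x) || any(!is.finite(x))) stop("measurements must be finite")
  t1 <- thresholds[["t1"]]; t2 <- thresholds[["t2"]]
  t3 <- thresholds[["t3"]]; t4 <- thresholds[["t4"]]
  out <- character(length(x))
  out[x <= t1] <- "-"
  out[x > t1 & x <= t2] <- "u-"
  out[x > t2 & x < t3] <- "0"
  out[x >= t3 & x < t4] <- "u+"
  out[x >= t4] <- "+"
  out
}

#' Construct an experimental profile
#'
#' An experimental profile holds the measured nodes with their discrete
#' observation labels, optionally the raw real-valued measurements they were
#' derived from, and the set of input (perturbed) nodes.  Inputs need not be
#' measured: in genome-scale studies the perturbed species are often unknown
#' and predecessor-free nodes are declared inputs without observations; an
#' unmeasured input has a free label.
#'
#' @param discrete named character vector of observation labels over the
#'   measured nodes (values in `"-", "u-", "0", "u+", "+"`), or NULL when
#'   `raw` is given.
#' @param inputs character vector of input node identifiers.
#' @param raw named numeric vector of raw measurements; when supplied
#'   together with `discrete` the names must agree, when supplied alone it is
#'   discretized with `thresholds`.
#' @param thresholds a [discretization_thresholds()] used when discretizing
#'   `raw`.
#' @return an object of class `experimental_profile` with components
#'   `measured`, `inputs`, `raw`, `discrete`.
#' @export
experimental_profile <- function(discrete = NULL, inputs = character(),
                                 raw = NULL, thresholds = default_thresholds()) {
  inputs <- sort(unique(as.character(inputs)))
  if (is.null(discrete)) {
    if (is.null(raw)) {
      discrete <- character() # inputs-only (or fully unconstrained) profile
    } else {
      if (is.null(names(raw)) || any(names(raw) == "")) stop("raw measurements must be named by node")
      if (anyDuplicated(names(raw))) stop("duplicate nodes in raw measurements")
      discrete <- stats::setNames(discretize_value(unname(raw), thresholds), names(raw))
    }
  } else {
    discrete <- unlist(discrete)
    if (length(discrete) && (is.null(names(discrete)) || any(names(discrete) == ""))) {
      stop("discrete observations must be named by node")
    }
    if (anyDuplicated(names(discrete))) stop("duplicate nodes in observations")
    check_obs_label(discrete)
    if (!is.null(raw)) {
      if (!setequal(names(raw), names(discrete))) {
        stop("raw and discrete observations must cover the same nodes")
      }
      raw <- raw[names(discrete)]
    }
  }
  measured <- sort(names(discrete))
  discrete <- discrete[measured]
  if (!is.null(raw)) raw <- raw[measured]
  structure(
    list(measured = measured, inputs = inputs, raw = raw, discrete = discrete),
    class = "experimental_profile"
  )
}

#' Discretize a full set of raw measurements into a profile
#'
#' @param raw named numeric vector of raw measurements (non-empty).
#' @param inputs character vector of input node identifiers.
#' @param thresholds a [discretization_thresholds()].
#' @return an [experimental_profile()].
#' @examples
#' discretize_profile(c(A = 2.5, B = -0.005), inputs = "A")
#' @export
discretize_profile <- function(raw, inputs = character(), thresholds = default_thresholds()) {
  if (length(raw) == 0L) stop("empty profile: no raw measurements")
  experimental_profile(raw = raw, inputs = inputs, thresholds = thresholds)
}

#' @export
print.experimental_profile <- function(x, ...) {
  cat(sprintf(
    "Experimental profile: %d measured node(s), %d input(s)%s\n",
    length(x$measured), length(x$inputs),
    if (is.null(x$raw)) "" else " (raw values attached)"
  ))
  if (length(x$measured)) {
    tab <- table(factor(x$discrete, levels = OBS_LABELS))
    cat("  observations:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}
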