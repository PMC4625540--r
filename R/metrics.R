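## Evaluation machinery: recovery rate, information gain, precision,
## confusion matrices, cross-validation and shuffle-null procedures.

#' Count prediction classes over a node set
#'
#' @param pm named character prediction map.
#' @param nodes node identifiers to count over (typically the unmeasured
#'   nodes).
#' @return list with `n` (nodes considered), `k` (strong predictions),
#'   `l` (weak predictions), `m` (no prediction); `k + l + m = n`.
#' @export
prediction_counts <- function(pm, nodes) {
  missing <- setdiff(nodes, names(pm))
  if (length(missing)) stop("prediction map missing node(s): ", paste(missing, collapse = ", "))
  p <- pm[nodes]
  list(
    n = length(p),
    k = sum(p %in% c("+", "-", "0")),
    l = sum(p %in% c("w+", "w-", "chg")),
    m = sum(p == "no")
  )
}

#' Recovery rate
#'
#' Fraction of the given (unmeasured) nodes for which any prediction,
#' strong or weak, is obtained.
#'
#' @inheritParams prediction_counts
#' @param unmeasured non-empty character vector of node identifiers.
#' @return fraction in `[0, 1]`.
#' @export
recovery_rate <- function(pm, unmeasured) {
  if (length(unmeasured) == 0L) stop("recovery rate undefined over an empty node set")
  counts <- prediction_counts(pm, unmeasured)
  (counts$k + counts$l) / counts$n
}

#' Information gain of a prediction map
#'
#' For n unconstrained nodes there are 3^n possible joint behaviors; a
#' strong prediction pins a node to 1, a weak prediction to 2, no prediction
#' leaves 3.  The log-scale reduction is
#' `(n log 3 - l log 2 - m log 3) / (n log 3)`,
#' which is 1 when all predictions are strong and 0 when none is made, and
#' is linear in the class counts.
#'
#' @param n number of nodes considered, or a list as returned by
#'   [prediction_counts()] (then `k`, `l`, `m` are taken from it).
#' @param k,l,m counts of strong, weak, and absent predictions;
#'   `k + l + m = n`.
#' @return fraction in `[0, 1]`.
#' @examples
#' information_gain(10000, k = 0, l = 774, m = 9226) # ~0.0286
#' @export
information_gain <- function(n, k = NULL, l = NULL, m = NULL) {
  if (is.list(n)) {
    counts <- n
    n <- counts$n; k <- counts$k; l <- counts$l; m <- counts$m
  }
  if (n <= 0) stop("information gain undefined for n = 0")
  if (k + l + m != n) stop("counts must satisfy k + l + m = n")
  (n * log(3) - l * log(2) - m * log(3)) / (n * log(3))
}

#' Validate one prediction against one observation
#'
#' A strong prediction is a true positive iff the certain measurement has
#' the same value; a weak prediction `"w+"` (`"w-"`, `"chg"`) is a true
#' positive iff the certain measurement is `+` or `0` (`-` or `0`, `+` or
#' `-`); any other certain measurement makes it a false positive.  Uncertain
#' measurements do not enter the TP/FP counts.
#'
#' @param pred a prediction label other than `"no"`.
#' @param obs an observation label.
#' @return one of `"TP"`, `"FP"`, `"uncounted"`.
#' @export
validate_prediction <- function(pred, obs) {
  if (!pred %in% PRED_LABELS || pred == "no") stop("not a prediction: ", pred)
  check_obs_label(obs)
  if (obs %in% c("u+", "u-")) return("uncounted")
  ok <- switch(pred,
    "+" = obs == "+",
    "-" = obs == "-",
    "0" = obs == "0",
    "w+" = obs %in% c("+", "0"),
    "w-" = obs %in% c("-", "0"),
    "chg" = obs %in% c("+", "-")
  )
  if (ok) "TP" else "FP"
}

#' Precision of a prediction map against validation observations
#'
#' TP / (TP + FP) overall and per prediction class, counting only nodes
#' with a prediction other than `"no"` and a certain validation
#' measurement.
#'
#' @param pm named character prediction map.
#' @param validation named character vector of observation labels.
#' @return list with `overall` (fraction) and `by_class` (named numeric,
#'   `NA` for classes with no counted pair), plus `tp` and `fp` counts.
#' @export
precision <- function(pm, validation) {
  common <- intersect(names(pm), names(validation))
  common <- common[pm[common] != "no"]
  status <- vapply(common, function(nm) validate_prediction(pm[[nm]], validation[[nm]]), character(1))
  counted <- common[status != "uncounted"]
  if (length(counted) == 0L) stop("no counted prediction/validation pair")
  tp <- sum(status[counted] == "TP")
  fp <- sum(status[counted] == "FP")
  classes <- setdiff(PRED_LABELS, "no")
  by_class <- stats::setNames(rep(NA_real_, length(classes)), classes)
  for (cl in classes) {
    sel <- counted[pm[counted] == cl]
    if (length(sel)) by_class[[cl]] <- mean(status[sel] == "TP")
  }
  list(overall = tp / (tp + fp), by_class = by_class, tp = tp, fp = fp)
}

#' Confusion matrix of predictions against observations
#'
#' Full cross-tabulation of predicted behavior (columns, including the
#' no-prediction class) against measured behavior (rows, including the
#' uncertain observation labels) over the validated nodes.
#'
#' @inheritParams precision
#' @return integer matrix with rows `"-", "u-", "0", "u+", "+"` and columns
#'   `"+", "-", "0", "w+", "w-", "chg", "no"`.
#' @export
confusion_matrix <- function(pm, validation) {
  common <- intersect(names(pm), names(validation))
  check_obs_label(validation[common])
  tab <- table(
    factor(validation[common], levels = OBS_LABELS),
    factor(pm[common], levels = PRED_LABELS)
  )
  m <- matrix(as.integer(tab), nrow = length(OBS_LABELS),
              dimnames = list(observed = OBS_LABELS, predicted = PRED_LABELS))
  m
}

## ---- cross-validation -----------------------------------------------------

#' Cross-validation of predictions on one profile
#'
#' Draws `n_samples` random subsets containing `ceiling(fraction * n)` of
#' the measurements (inputs are kept unchanged), computes predictions under
#' minimal correction sets from each reduced profile, and validates them
#' against the held-out measurements.  Per-sample recovery, information
#' gain and precision are aggregated as unweighted means; confusion
#' matrices are summed.
#'
#' @inheritParams mcos
#' @param fraction share of the measurements given to the predictor, in
#'   `(0, 1]`.  With `fraction = 1` there is no validation data and the
#'   report flags it.
#' @param n_samples number of random subsamples.
#' @param seed integer seed fixing the subsampling.
#' @param max_repairs cap on repair cardinality per sample.
#' @return an object of class `sc_eval`: list with `samples` (one row per
#'   sample: recovery, info_gain, precision, tp, fp, n_predicted),
#'   `recovery`, `info_gain`, `precision_overall`, `precision_by_class`,
#'   `confusion` (summed counts), `no_validation` flag, and the call
#'   parameters.
#' @export
crossval <- function(graph, profile, fraction = 0.1, n_samples = 10L,
                     notion = "FSP", seed = 1L, max_repairs = 32L) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  if (length(profile$measured) < 2L) stop("cross-validation needs at least 2 measurements")
  profile <- reconcile(graph, profile)
  n_take <- ceiling(fraction * length(profile$measured))
  nodes <- setdiff(graph$nodes, graph$artificial)

  rng <- make_rng(seed)
  samples <- vector("list", n_samples)
  confusion <- matrix(0L, length(OBS_LABELS), length(PRED_LABELS),
                      dimnames = list(observed = OBS_LABELS, predicted = PRED_LABELS))
  by_class_tp <- stats::setNames(numeric(6), setdiff(PRED_LABELS, "no"))
  by_class_n <- by_class_tp

  for (s in seq_len(n_samples)) {
    take <- rng$sample(profile$measured, n_take)
    held_out <- setdiff(profile$measured, take)
    reduced <- experimental_profile(
      discrete = profile$discrete[take], inputs = profile$inputs
    )
    pm <- predict_under_mcos(graph, reduced, notion, max_size = max_repairs)
    unmeasured <- setdiff(nodes, take)
    counts <- prediction_counts(pm, unmeasured)
    rec <- if (counts$n) (counts$k + counts$l) / counts$n else NA_real_
    ig <- if (counts$n) information_gain(counts) else NA_real_

    prec <- NA_real_; tp <- NA_integer_; fp <- NA_integer_
    if (length(held_out)) {
      val <- profile$discrete[held_out]
      confusion <- confusion + confusion_matrix(pm, val)
      pr <- tryCatch(precision(pm, val), error = function(e) NULL)
      if (!is.null(pr)) {
        prec <- pr$overall; tp <- pr$tp; fp <- pr$fp
        for (cl in names(by_class_tp)) {
          if (!is.na(pr$by_class[[cl]])) {
            sel <- intersect(names(pm)[pm == cl], held_out)
            sel <- sel[val[sel] %in% c("+", "-", "0")]
            by_class_tp[[cl]] <- by_class_tp[[cl]] + sum(
              vapply(sel, function(nm) validate_prediction(cl, val[[nm]]) == "TP", logical(1))
            )
            by_class_n[[cl]] <- by_class_n[[cl]] + length(sel)
          }
        }
      }
    }
    samples[[s]] <- data.frame(
      sample = s, recovery = rec, info_gain = ig, precision = prec,
      tp = tp, fp = fp, n_predicted = counts$k + counts$l
    )
  }
  samples <- do.call(rbind, samples)
  structure(
    list(
      samples = samples,
      recovery = mean(samples$recovery, na.rm = TRUE),
      info_gain = mean(samples$info_gain, na.rm = TRUE),
      precision_overall = if (all(is.na(samples$precision))) NA_real_
                          else mean(samples$precision, na.rm = TRUE),
      precision_by_class = ifelse(by_class_n > 0, by_class_tp / by_class_n, NA_real_),
      confusion = confusion,
      no_validation = n_take >= length(profile$measured),
      fraction = fraction, n_samples = n_samples, notion = notion, seed = seed
    ),
    class = "sc_eval"
  )
}

#' @export
print.sc_eval <- function(x, ...) {
  cat(sprintf(
    "Cross-validation (%s, fraction %.2f, %d samples)\n",
    x$notion, x$fraction, x$n_samples
  ))
  if (x$no_validation) cat("  NOTE: fraction = 1, no validation data\n")
  cat(sprintf("  mean recovery: %.3f  mean information gain: %.3f\n", x$recovery, x$info_gain))
  if (!is.na(x$precision_overall)) {
    cat(sprintf("  mean precision: %.3f\n", x$precision_overall))
  }
  invisible(x)
}

## ---- shuffle null ---------------------------------------------------------

#' Shuffle-null distribution of the inconsistency index
#'
#' Compares the inconsistency index of the real profile to profiles whose
#' observed labels are randomly permuted among the measured nodes (the
#' label multiset, hence the sign distribution, is preserved).  For a single
#' profile the empirical quantile of the real index within the null is
#' reported; for a list of profiles the per-profile real indices are
#' compared with the per-profile mean shuffled indices by a paired Wilcoxon
#' signed-rank test (one-sided: real less inconsistent than shuffled).
#'
#' @inheritParams mcos
#' @param profile an [experimental_profile()] or a list of them.
#' @param n_shuffles number of permuted profiles per experiment (>= 1).
#' @param seed integer seed for the permutations.
#' @param max_repairs cap on repair cardinality.
#' @return list of class `sc_null` with components `real` (index or vector
#'   of indices), `shuffled` (vector, or matrix profiles x shuffles),
#'   `p_value`, and `degenerate` (TRUE when all observed labels are equal so
#'   every permutation is identical).
#' @export
null_distribution <- function(graph, profile, n_shuffles = 100L,
                              notion = "FSP", seed = 1L, max_repairs = 32L) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  profiles <- if (inherits(profile, "experimental_profile")) list(profile) else profile
  stopifnot(all(vapply(profiles, inherits, logical(1), "experimental_profile")))
  rng <- make_rng(seed)

  real <- numeric(length(profiles))
  shuffled <- matrix(NA_real_, length(profiles), n_shuffles)
  degenerate <- logical(length(profiles))
  for (pi in seq_along(profiles)) {
    p <- reconcile(graph, profiles[[pi]])
    real[[pi]] <- inconsistency_index(graph, p, notion, max_size = max_repairs)
    degenerate[[pi]] <- length(unique(p$discrete)) <= 1L
    for (s in seq_len(n_shuffles)) {
      perm <- rng$sample(p$discrete, length(p$discrete))
      shuf <- experimental_profile(
        discrete = stats::setNames(unname(perm), p$measured),
        inputs = p$inputs
      )
      shuffled[pi, s] <- inconsistency_index(graph, shuf, notion, max_size = max_repairs)
    }
  }
  if (length(profiles) == 1L) {
    shuf_vec <- shuffled[1L, ]
    p_value <- if (degenerate[[1L]]) NA_real_ else {
      (1 + sum(shuf_vec <= real[[1L]])) / (n_shuffles + 1)
    }
    out <- list(real = real[[1L]], shuffled = shuf_vec, p_value = p_value,
                degenerate = degenerate[[1L]])
  } else {
    shuf_means <- rowMeans(shuffled)
    p_value <- stats::wilcox.test(real, shuf_means, paired = TRUE,
                                  alternative = "less", exact = FALSE)$p.value
    out <- list(real = real, shuffled = shuffled, shuffled_means = shuf_means,
                p_value = p_value, degenerate = degenerate)
  }
  structure(c(out, list(n_shuffles = n_shuffles, notion = notion, seed = seed)),
            class = "sc_null")
}

#' @export
print.sc_null <- function(x, ...) {
  if (length(x$real) == 1L) {
    cat(sprintf(
      "Shuffle null (%s, %d shuffles): real index %.4g, null mean %.4g\n",
      x$notion, x$n_shuffles, x$real, mean(x$shuffled)
    ))
    if (isTRUE(x$degenerate)) cat("  NOTE: degenerate null (constant observed labels)\n")
    if (!is.na(x$p_value)) cat(sprintf("  empirical p-value: %.4g\n", x$p_value))
  } else {
    cat(sprintf(
      "Shuffle null over %d profiles (%s, %d shuffles each): paired Wilcoxon p = %.4g\n",
      length(x$real), x$notion, x$n_shuffles, x$p_value
    ))
  }
  invisible(x)
}
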