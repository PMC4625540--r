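test_that("recovery rate counts strong and weak predictions alike", {
  expect_equal(recovery_rate(c(B = "+", C = "no"), c("B", "C")), 0.5)
  expect_equal(recovery_rate(c(B = "no", C = "no"), c("B", "C")), 0)
  expect_equal(recovery_rate(c(B = "w+"), "B"), 1)
  expect_error(recovery_rate(c(B = "+"), character()), "empty")
  expect_error(recovery_rate(c(B = "+"), c("B", "Z")), "missing")
})

test_that("information gain matches its closed form and is linear", {
  expect_equal(information_gain(100, k = 100, l = 0, m = 0), 1)
  expect_equal(information_gain(100, k = 0, l = 0, m = 100), 0)
  # printed weak-coverage fractions reproduce the printed gains (2 decimals)
  expect_equal(round(100 * information_gain(10000, k = 0, l = 774, m = 9226), 2), 2.86)
  expect_equal(round(100 * information_gain(10000, k = 0, l = 1314, m = 8686), 2), 4.85)
  expect_equal(round(100 * information_gain(10000, k = 0, l = 2899, m = 7101), 2), 10.70)
  # additivity: strong-only plus weak-only equals the combined gain
  n <- 400L; k <- 37L; l <- 101L; m <- n - k - l
  expect_equal(
    information_gain(n, k, 0L, n - k) + information_gain(n, 0L, l, n - l),
    information_gain(n, k, l, m)
  )
  expect_error(information_gain(0, 0, 0, 0), "n = 0")
  expect_error(information_gain(10, 1, 1, 1), "k \\+ l \\+ m")
})

test_that("prediction validation against certain and uncertain observations", {
  expect_identical(validate_prediction("+", "+"), "TP")
  expect_identical(validate_prediction("+", "0"), "FP")
  expect_identical(validate_prediction("0", "0"), "TP")
  expect_identical(validate_prediction("w+", "0"), "TP")
  expect_identical(validate_prediction("w+", "+"), "TP")
  expect_identical(validate_prediction("w+", "-"), "FP")
  expect_identical(validate_prediction("w-", "-"), "TP")
  expect_identical(validate_prediction("chg", "+"), "TP")
  expect_identical(validate_prediction("chg", "0"), "FP")
  expect_identical(validate_prediction("chg", "u+"), "uncounted")
  expect_identical(validate_prediction("+", "u-"), "uncounted")
  expect_error(validate_prediction("no", "+"), "not a prediction")
})

test_that("precision aggregates TP/(TP+FP) overall and by class", {
  pr <- precision(c(B = "+"), c(B = "+"))
  expect_equal(pr$overall, 1)
  pr2 <- precision(c(B = "+", C = "w+"), c(B = "+", C = "-"))
  expect_equal(pr2$overall, 0.5)
  expect_equal(pr2$by_class[["+"]], 1)
  expect_equal(pr2$by_class[["w+"]], 0)
  expect_error(precision(c(B = "w+"), c(B = "u-")), "no counted")
  # removing a false positive never decreases precision
  pr3 <- precision(c(B = "+"), c(B = "+", C = "-"))
  expect_gte(pr3$overall, pr2$overall)
})

test_that("confusion matrix cross-tabulates all classes and conserves counts", {
  cm <- confusion_matrix(c(B = "+"), c(B = "+"))
  expect_equal(cm["+", "+"], 1L)
  expect_equal(sum(cm), 1L)
  cm2 <- confusion_matrix(c(B = "no", C = "w-", D = "+"),
                          c(B = "0", C = "u-", D = "-", E = "+"))
  expect_equal(sum(cm2), 3L) # only nodes with both a prediction entry and validation
  expect_equal(cm2["0", "no"], 1L)
  expect_equal(cm2["u-", "w-"], 1L)
  expect_equal(cm2["-", "+"], 1L)
})

test_that("cross-validation is seeded, deterministic and sound on noiseless data", {
  inst <- sample_instance(synth_config(
    n_nodes = 9L, n_edges = 12L, frac_observed = 0.9,
    frac_uncertain = 0, noise_flips = 0, notion = "FSP", seed = 42L
  ))
  cv1 <- crossval(inst$graph, inst$profile, fraction = 0.4, n_samples = 4L,
                  notion = "FSP", seed = 7L)
  cv2 <- crossval(inst$graph, inst$profile, fraction = 0.4, n_samples = 4L,
                  notion = "FSP", seed = 7L)
  expect_identical(cv1$samples, cv2$samples)
  expect_identical(cv1$confusion, cv2$confusion)
  # noiseless: cautious predictions can never contradict the hidden labeling
  expect_equal(cv1$precision_overall, 1)
  expect_true(all(stats::na.omit(cv1$samples$precision) == 1))
  # fraction = 1 leaves nothing to validate
  cv3 <- crossval(inst$graph, inst$profile, fraction = 1, n_samples = 2L,
                  notion = "FSP", seed = 7L)
  expect_true(cv3$no_validation)
  expect_true(is.na(cv3$precision_overall))
  expect_error(crossval(inst$graph, inst$profile, fraction = 0), "fraction")
})

test_that("more data can only help recovery on average (noiseless)", {
  inst <- sample_instance(synth_config(
    n_nodes = 9L, n_edges = 14L, frac_observed = 0.9,
    frac_uncertain = 0, noise_flips = 0, notion = "FSP", seed = 11L
  ))
  cv_lo <- crossval(inst$graph, inst$profile, fraction = 0.2, n_samples = 6L,
                    notion = "FSP", seed = 5L)
  cv_hi <- crossval(inst$graph, inst$profile, fraction = 0.7, n_samples = 6L,
                    notion = "FSP", seed = 5L)
  expect_lte(cv_lo$recovery, cv_hi$recovery + 1e-9)
})

test_that("shuffle null permutes labels but preserves their multiset", {
  fx <- toy_fixtures()
  nd <- null_distribution(fx$fork$graph, fx$fork$profile, n_shuffles = 8L,
                          notion = "FSP", seed = 3L)
  expect_equal(nd$real, 0.5)
  expect_length(nd$shuffled, 8L)
  expect_true(all(nd$shuffled >= 0))
  expect_false(nd$degenerate)
  expect_true(nd$p_value > 0 && nd$p_value <= 1)
  expect_error(null_distribution(fx$fork$graph, fx$fork$profile, n_shuffles = 0L),
               "n_shuffles")
  # constant labels: every permutation identical, flagged degenerate
  g <- fx$chain$graph
  p <- experimental_profile(c(A = "+", B = "+"), inputs = "A")
  nd2 <- null_distribution(g, p, n_shuffles = 4L, notion = "WP", seed = 1L)
  expect_true(nd2$degenerate)
  expect_true(all(nd2$shuffled == nd2$real))
  # multi-profile mode: paired rank test across experiments
  insts <- lapply(1:4, function(s) sample_instance(synth_config(
    n_nodes = 7L, n_edges = 10L, frac_observed = 0.8, frac_uncertain = 0,
    noise_flips = 0, notion = "FSP", seed = 50L + s
  )))
  g1 <- insts[[1]]$graph
  nd3 <- null_distribution(g1, lapply(insts, `[[`, "profile"),
                           n_shuffles = 3L, notion = "FSP", seed = 2L)
  expect_length(nd3$real, 4L)
  expect_true(nd3$p_value > 0 && nd3$p_value <= 1)
})
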