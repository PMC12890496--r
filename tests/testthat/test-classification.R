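sim_freq <- function(n_e = 12, n_l = 16, sep = 0.6, seed = 1) {
  set.seed(seed)
  donors <- sprintf("D%02d", seq_len(n_e + n_l))
  labels <- setNames(rep(c("EOMG", "LOMG"), c(n_e, n_l)), donors)
  lf <- cbind(c(rnorm(n_e, 1, 0.1), rnorm(n_l, 1 - sep, 0.1)),
              rnorm(n_e + n_l, 0.5, 0.1),
              rnorm(n_e + n_l, 0.2, 0.1))
  freq <- 10^lf - 0.01
  dimnames(freq) <- list(donors, c("CD8T#1", "CD8T#2", "NK#3"))
  list(freq = freq, labels = labels)
}

test_that("a single discriminating cluster dominates the weight vector", {
  d <- sim_freq(sep = 0.6)   # 6 within-group SDs of separation
  model <- fit_plsda(d$freq, d$labels)
  infl <- influence_fractions(model)
  expect_gt(infl[["CD8T#1"]], 0.8)
  expect_equal(sum(infl), 1)
  expect_gt(model$weights[["CD8T#1"]], 0)  # EOMG-high orientation
})

test_that("label flips negate the axis and duplication keeps the direction", {
  d <- sim_freq(seed = 2)
  m1 <- fit_plsda(d$freq, d$labels)
  flipped <- setNames(ifelse(d$labels == "EOMG", "LOMG", "EOMG"),
                      names(d$labels))
  m2 <- fit_plsda(d$freq, flipped)
  expect_equal(m2$weights, -m1$weights)
  expect_equal(abs(m2$train_scores$score), abs(m1$train_scores$score))

  dup <- rbind(d$freq, d$freq)
  rownames(dup) <- c(rownames(d$freq), paste0(rownames(d$freq), "b"))
  lab_dup <- setNames(rep(d$labels, 2), rownames(dup))
  m3 <- fit_plsda(dup, lab_dup)
  expect_equal(m3$weights, m1$weights, tolerance = 1e-10)
  expect_equal(influence_fractions(m3), influence_fractions(m1),
               tolerance = 1e-10)

  const <- d$freq; const[, 2] <- 5
  expect_error(fit_plsda(const, d$labels), "constant predictor")
  expect_error(fit_plsda(d$freq[1:3, ], d$labels[1:3]), "2 donors")
})

test_that("influence fractions are normalized absolute weights", {
  model <- structure(list(weights = c(a = 0.5, b = -0.5, c = 0)),
                     class = "plsda_model")
  expect_equal(influence_fractions(model), c(a = 0.5, b = 0.5, c = 0))
  expect_error(influence_fractions(structure(list(weights = c(a = 0)),
                                             class = "plsda_model")),
               "zero weight")
})

test_that("the decision threshold bisects the class means", {
  scores <- c(2, 2, -2, -2)
  labels <- c("EOMG", "EOMG", "LOMG", "LOMG")
  expect_equal(decision_threshold(scores, labels), 0)
  expect_equal(decision_threshold(scores + 1.5, labels), 1.5)
  expect_error(decision_threshold(scores[1:2], labels[1:2]), "absent")
  # perfectly separated training scores classify without error
  d <- sim_freq(sep = 1, seed = 3)
  model <- fit_plsda(d$freq, d$labels)
  pred <- classify_samples(model, d$freq)
  expect_equal(pred$label, unname(d$labels[pred$donor_id]))
})

test_that("classification is deterministic, ties go to LOMG, missing data are flagged", {
  d <- sim_freq(seed = 4)
  model <- fit_plsda(d$freq, d$labels)
  p1 <- classify_samples(model, d$freq)
  p2 <- classify_samples(model, d$freq)
  expect_identical(p1, p2)
  expect_equal(p1$score, model$train_scores$score)

  tie_model <- structure(list(cluster_ids = "CD8T#1", log_offset = 0.01,
                              center = c("CD8T#1" = 0),
                              scale = c("CD8T#1" = 1),
                              weights = c("CD8T#1" = 1), threshold = 0.5),
                         class = "plsda_model")
  tie_freq <- matrix(10^0.5 - 0.01, 1, 1,
                     dimnames = list("Dx", "CD8T#1"))
  expect_equal(classify_samples(tie_model, tie_freq)$label, "LOMG")

  na_freq <- d$freq
  na_freq[1, 2] <- NA
  pna <- classify_samples(model, na_freq)
  expect_true(is.na(pna$label[1]))
  expect_error(classify_samples(model, d$freq[, 1:2]), "lacks model")
})

test_that("confusion arithmetic reproduces the reported rates", {
  truth <- rep(c("EOMG", "LOMG"), c(12, 16))
  pred <- c(rep("EOMG", 10), rep("LOMG", 2), rep("LOMG", 16))
  cs <- confusion_stats(pred, truth)
  expect_equal(c(cs$TP, cs$FN, cs$TN, cs$FP), c(10, 2, 16, 0))
  expect_equal(cs$sensitivity_pct, 83)
  expect_equal(cs$specificity_pct, 100)

  truth2 <- rep(c("EOMG", "LOMG"), c(8, 6))
  pred2 <- c(rep("EOMG", 8), "EOMG", rep("LOMG", 5))
  cs2 <- confusion_stats(pred2, truth2)
  expect_equal(c(cs2$TP, cs2$FN, cs2$TN, cs2$FP), c(8, 0, 5, 1))
  expect_equal(cs2$sensitivity_pct, 100)
  expect_equal(cs2$specificity_pct, 83)

  cs3 <- confusion_stats(truth, truth)
  expect_equal(cs3$sensitivity_pct, 100)
  expect_equal(cs3$specificity_pct, 100)
  expect_equal(cs3$accuracy, 1)
  expect_error(confusion_stats(setNames(pred, paste0("d", 1:28)),
                               setNames(truth, paste0("e", 1:28))),
               "different donor sets")
})

test_that("ROC area equals the pairwise Mann-Whitney probability", {
  scores <- c(3, 2.5, 2, 1, 0.5)
  labels <- c("EOMG", "EOMG", "LOMG", "LOMG", "LOMG")
  expect_equal(roc_points(scores, labels)$auc, 1)
  expect_equal(roc_points(rep(1, 6),
                          rep(c("EOMG", "LOMG"), 3))$auc, 0.5)
  set.seed(15)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    sc <- sample(seq(0, 4, by = 0.5), n, replace = TRUE)  # with ties
    lb <- sample(c("EOMG", "LOMG"), n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_points(sc, lb)$auc, enum_auc(sc, lb))
  }
  expect_error(roc_points(1:3, rep("EOMG", 3)), "both classes")
})

test_that("the fitted direction agrees with a reference PLS-DA", {
  skip_if_not_installed("mixOmics")
  d <- sim_freq(seed = 6)
  model <- fit_plsda(d$freq, d$labels)
  x <- scale(log10(d$freq + 0.01))
  ref <- mixOmics::plsda(x, factor(d$labels), ncomp = 1)
  w_ref <- ref$loadings$X[, 1]
  alignment <- abs(sum(w_ref * model$weights) /
                     sqrt(sum(w_ref^2) * sum(model$weights^2)))
  expect_gt(alignment, 0.999)
})

test_that("models survive a JSON round trip", {
  d <- sim_freq(seed = 7)
  model <- fit_plsda(d$freq, d$labels)
  path <- tempfile(fileext = ".json")
  write_plsda(model, path)
  back <- read_plsda(path)
  expect_equal(back$weights, model$weights)
  expect_equal(back$threshold, model$threshold)
  expect_equal(classify_samples(back, d$freq)$score,
               classify_samples(model, d$freq)$score)
  unlink(path)
})
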