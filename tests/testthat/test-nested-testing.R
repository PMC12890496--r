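make_catalog <- function(clusters, lineages) {
  structure(list(
    clusters = data.frame(cluster_id = clusters, lineage = lineages,
                          n_cells_train = NA_integer_,
                          stringsAsFactors = FALSE),
    assignments = data.frame(cell_id = character(0),
                             donor_id = character(0),
                             lineage = character(0),
                             cluster_id = character(0),
                             stringsAsFactors = FALSE)),
    class = "cluster_catalog")
}

test_that("cluster frequencies are percentages of the parent lineage", {
  cells <- data.frame(
    cell_id = sprintf("c%03d", 1:260),
    donor_id = rep(c("A", "B"), c(200, 60)),
    cohort = "discovery", tissue = "blood",
    lineage = c(rep("CD8T", 200), rep("CD8T", 60)),
    cluster = NA_character_, true_subpop = "background",
    stringsAsFactors = FALSE)
  catalog <- make_catalog(c("CD8T#1", "NK#2"), c("CD8T", "NK"))
  ass <- data.frame(cell_id = cells$cell_id[1:18], donor_id = "A",
                    cluster_id = "CD8T#1", stringsAsFactors = FALSE)
  freq <- cluster_frequencies(cells, catalog, assignments = ass)
  expect_equal(freq["A", "CD8T#1"], 9)
  expect_equal(freq["B", "CD8T#1"], 0)
  # a donor with no parent-lineage cells is missing, not zero
  expect_true(is.na(freq["A", "NK#2"]))
  expect_true(all(freq[!is.na(freq)] >= 0 & freq[!is.na(freq)] <= 100))
})

test_that("the direction rule picks the lowest patient-group median", {
  freq <- matrix(c(rep(2, 4), rep(6, 4), rep(5, 4)), ncol = 1,
                 dimnames = list(sprintf("D%02d", 1:12), "CD8T#1"))
  meta <- data.frame(donor_id = sprintf("D%02d", 1:12),
                     group = rep(c("EOMG", "LOMG", "CTRL"), each = 4),
                     stringsAsFactors = FALSE)
  expect_equal(assign_direction(freq, meta)$direction, "EOMG")
  freq2 <- freq
  freq2[meta$group == "EOMG", 1] <- 6
  freq2[meta$group == "LOMG", 1] <- 2
  expect_equal(assign_direction(freq2, meta)$direction, "LOMG")
  # controls lowest: no patient-group direction
  freq3 <- freq
  freq3[, 1] <- rep(c(5, 6, 2), each = 4)
  expect_true(is.na(assign_direction(freq3, meta)$direction))
  # a group with no non-missing donors is an error
  freq4 <- freq
  freq4[meta$group == "CTRL", 1] <- NA
  expect_error(assign_direction(freq4, meta), "zero non-missing")
})

test_that("one-tailed rank-sum p-values match exact enumeration", {
  expect_equal(rank_sum_one_tailed(1:4, 5:8, "less"), 1 / 70)
  expect_equal(rank_sum_one_tailed(c(1, 3), c(2, 4), "less"), 1 / 3)
  set.seed(11)
  for (i in 1:10) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    z <- sample(100, m + n)
    x <- z[1:m]; y <- z[-(1:m)]
    expect_equal(rank_sum_one_tailed(x, y, "less"),
                 enum_ranksum_p(x, y, "less"))
    expect_equal(rank_sum_one_tailed(x, y, "greater"),
                 enum_ranksum_p(x, y, "greater"))
    # discreteness: the two tails overlap at the observed statistic
    expect_gte(rank_sum_one_tailed(x, y, "less") +
                 rank_sum_one_tailed(x, y, "greater"), 1)
  }
  expect_error(rank_sum_one_tailed(numeric(0), 1:3), "non-empty")
})

test_that("the tie-corrected approximation agrees with wilcox.test", {
  set.seed(12)
  for (i in 1:10) {
    x <- sample(1:8, 15, replace = TRUE)
    y <- sample(2:9, 12, replace = TRUE)
    ref <- suppressWarnings(
      wilcox.test(x, y, alternative = "less", exact = FALSE,
                  correct = TRUE))$p.value
    expect_equal(rank_sum_one_tailed(x, y, "less"), ref,
                 tolerance = 1e-12)
  }
})

test_that("nested selection requires all three comparisons", {
  expect_true(nested_select(0.04, 0.01, 0.03))
  expect_false(nested_select(0.04, 0.06, 0.001))
  expect_false(nested_select(0.05, 0.01, 0.01))   # strict inequality
  expect_error(nested_select(0, 0.01, 0.01), "p-values")
  expect_error(nested_select(0.01, 1.2, 0.01), "p-values")
})

test_that("selection is invariant under monotone frequency transforms", {
  set.seed(13)
  donors <- sprintf("D%02d", 1:26)
  meta <- data.frame(donor_id = donors,
                     group = rep(c("EOMG", "LOMG", "CTRL"), c(8, 8, 10)),
                     stringsAsFactors = FALSE)
  freq <- matrix(runif(26 * 3, 1, 9), 26, 3,
                 dimnames = list(donors, paste0("CD8T#", 1:3)))
  freq[meta$group == "LOMG", 1] <- freq[meta$group == "LOMG", 1] / 4
  vd <- sprintf("V%02d", 1:10)
  metav <- data.frame(donor_id = vd,
                      group = rep(c("EOMG", "LOMG"), c(5, 5)),
                      stringsAsFactors = FALSE)
  fv <- matrix(runif(10 * 3, 1, 9), 10, 3,
               dimnames = list(vd, paste0("CD8T#", 1:3)))
  fv[metav$group == "LOMG", 1] <- fv[metav$group == "LOMG", 1] / 4
  meta_all <- rbind(meta, metav)
  r1 <- nested_test_clusters(freq, fv, meta_all)
  r2 <- nested_test_clusters(freq^(1 / 3), fv^(1 / 3), meta_all)
  expect_equal(r1$selected, r2$selected)
  expect_equal(r1[, c("p_train_case", "p_train_ctrl", "p_val_case")],
               r2[, c("p_train_case", "p_train_ctrl", "p_val_case")])
  # the planted LOMG-low cluster is found, with a consistent direction
  expect_true(r1$selected[1])
  expect_equal(r1$direction[1], "LOMG")
})

test_that("the error-rate calculus reproduces the design arithmetic", {
  res <- error_rate_calculus(0.05, 3, 11)
  expect_equal(res$nested_rate, 0.000125)
  expect_equal(res$nested_one_in, 8000)
  expect_equal(res$bonferroni_alpha, 0.05 / 11)
  expect_equal(res$bonferroni_one_in, 220)
  expect_equal(res$combined_rate, 0.000125 / 11)
  expect_equal(res$combined_one_in, 88000)
  expect_error(error_rate_calculus(0), "alpha")
})

test_that("BH adjustment matches the hand step-up and its properties", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(14)
  for (i in 1:10) {
    p <- runif(sample(2:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, enum_bh(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.1, 0)), "p-values")
})

test_that("the vectorized null simulation matches the test implementation", {
  # the simulated U statistics must convert to the very p-values
  # rank_sum_one_tailed produces for the same data
  set.seed(15)
  for (sizes in list(c(12, 16), c(12, 20), c(8, 6))) {
    for (i in 1:20) {
      x <- runif(sizes[1]); y <- runif(sizes[2])
      U <- sum(outer(x, y, ">"))
      expect_equal(mgendo:::.p_less_from_U(U, sizes[1], sizes[2]),
                   rank_sum_one_tailed(x, y, "less"), tolerance = 1e-12)
    }
  }
  r <- null_selection_rate(n_reps = 2000, seed = 5)
  expect_gte(r$rate, 0)
  expect_equal(r$n_reps, 2000)
})
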