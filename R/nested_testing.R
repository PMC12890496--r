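## Donor-level cluster frequencies, directional hypothesis assignment, the
## nested one-tailed Wilcoxon selection rule, and the false-positive
## error-rate calculus.

#' Donor-level cluster frequencies relative to the parent lineage
#'
#' For every donor, a cluster's frequency is 100 x (cells assigned to the
#' cluster) / (cells of the cluster's parent lineage), as a percentage.
#' Donors with zero parent-lineage cells get a missing value (not zero) and
#' are excluded from downstream tests.
#'
#' @param cells cell table providing the parent-lineage denominators (all
#'   gated cells of the cohort/tissue of interest).
#' @param catalog a `cluster_catalog` defining clusters and parent lineages.
#' @param assignments cell-to-cluster assignment data frame with columns
#'   `cell_id`, `donor_id`, `cluster_id`; defaults to the catalog's training
#'   assignments, pass [transfer_labels()]`$assignments` for a validation
#'   cohort.
#' @return numeric matrix donors x clusters (percent of parent lineage) with
#'   a `lineage` attribute naming each cluster's parent.
#' @export
cluster_frequencies <- function(cells, catalog, assignments = NULL) {
  stopifnot(inherits(catalog, "cluster_catalog"))
  if (is.null(assignments)) assignments <- catalog$assignments
  donors <- sort(unique(cells$donor_id))
  cl <- catalog$clusters
  lin_counts <- table(factor(cells$donor_id, donors),
                      factor(cells$lineage, .LINEAGES))
  ass <- assignments[!is.na(assignments$cluster_id), , drop = FALSE]
  num <- table(factor(ass$donor_id, donors),
               factor(ass$cluster_id, cl$cluster_id))
  freq <- matrix(NA_real_, length(donors), nrow(cl),
                 dimnames = list(donors, cl$cluster_id))
  for (j in seq_len(nrow(cl))) {
    den <- lin_counts[, cl$lineage[j]]
    freq[, j] <- ifelse(den > 0, 100 * num[, j] / den, NA_real_)
  }
  attr(freq, "lineage") <- setNames(cl$lineage, cl$cluster_id)
  freq
}

#' Assign each cluster's directional hypothesis from training data
#'
#' The group of interest is the patient group (EOMG or LOMG) whose median
#' training frequency is lowest; the directional hypothesis is that this
#' group is LOW, and only that direction is ever tested. Clusters whose
#' lowest median belongs to the controls (or is tied) have no patient-group
#' direction and are flagged ineligible (`NA`).
#'
#' @param freq_train donors x clusters frequency matrix (training cohort).
#' @param meta donor metadata with `donor_id` and `group`.
#' @return data frame: `cluster_id`, `direction` (`"EOMG"`, `"LOMG"` or
#'   `NA`), and the three group medians.
#' @export
assign_direction <- function(freq_train, meta) {
  groups <- c("EOMG", "LOMG", "CTRL")
  grp <- meta$group[match(rownames(freq_train), meta$donor_id)]
  out <- data.frame(cluster_id = colnames(freq_train),
                    direction = NA_character_,
                    median_EOMG = NA_real_, median_LOMG = NA_real_,
                    median_CTRL = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(freq_train))) {
    med <- vapply(groups, function(g) {
      v <- freq_train[grp == g, j]
      v <- v[!is.na(v)]
      if (length(v) == 0L) {
        stop("group ", g, " has zero non-missing donors for cluster ",
             colnames(freq_train)[j])
      }
      median(v)
    }, 0)
    out$median_EOMG[j] <- med["EOMG"]
    out$median_LOMG[j] <- med["LOMG"]
    out$median_CTRL[j] <- med["CTRL"]
    lowest <- names(med)[med == min(med)]
    if (length(lowest) == 1L && lowest %in% .PATIENT_GROUPS) {
      out$direction[j] <- lowest
    }
  }
  out
}

# one-tailed p for the Mann-Whitney U statistic of x vs y without ties:
# exact tail when the combined sample is small, tie-free normal
# approximation with continuity correction otherwise. Used by the
# vectorized null simulation so it matches rank_sum_one_tailed exactly.
.p_less_from_U <- function(U, m, n) {
  if (m + n <= 20) {
    pwilcox(U, m, n)
  } else {
    mu <- m * n / 2
    sigma <- sqrt(m * n * (m + n + 1) / 12)
    pmin(1, pnorm((U + 0.5 - mu) / sigma))
  }
}

#' One-tailed Wilcoxon rank-sum test
#'
#' Exact-enumeration p-value when the combined sample size is at most 20 and
#' there are no ties; otherwise a normal approximation with midranks,
#' tie-corrected variance and continuity correction. `tail = "less"` tests
#' the hypothesis that `x` is stochastically smaller than `y`.
#'
#' @param x,y non-empty numeric samples (missing values dropped).
#' @param tail `"less"` or `"greater"`.
#' @return p-value in (0, 1].
#' @export
rank_sum_one_tailed <- function(x, y, tail = c("less", "greater")) {
  tail <- match.arg(tail)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (m + n <= 20 && !has_ties) {
    p <- if (tail == "less") pwilcox(U, m, n)
         else pwilcox(m * n - U, m, n)
  } else {
    mu <- m * n / 2
    tie_term <- sum(ties^3 - ties) / ((m + n) * (m + n - 1))
    sigma <- sqrt(m * n / 12 * (m + n + 1 - tie_term))
    z <- if (tail == "less") (U + 0.5 - mu) / sigma
         else (U - 0.5 - mu) / sigma
    p <- if (tail == "less") pnorm(z) else 1 - pnorm(z)
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Nested three-test selection rule
#'
#' A cluster is selected if and only if all three one-tailed comparisons —
#' training case vs case, training group-of-interest vs controls, and
#' validation case vs case — are significant at `alpha`.
#'
#' @param p1,p2,p3 the three one-tailed p-values, each in (0, 1].
#' @param alpha per-test significance level.
#' @return logical.
#' @export
nested_select <- function(p1, p2, p3, alpha = 0.05) {
  .assert_pvalues(c(p1, p2, p3))
  max(p1, p2, p3) < alpha
}

#' Run the nested directional tests on every cluster
#'
#' Directions are assigned from the training cohort by
#' [assign_direction()]; for each directed cluster the three one-tailed
#' rank-sum comparisons are computed and combined by [nested_select()].
#' Clusters without a patient-group direction are reported unselected with
#' missing p-values.
#'
#' @param freq_train,freq_val donors x clusters frequency matrices for the
#'   two cohorts (same clusters).
#' @param meta donor metadata covering both cohorts.
#' @param alpha per-test significance level.
#' @return data frame with one row per cluster: direction, the three
#'   p-values and the `selected` flag.
#' @export
nested_test_clusters <- function(freq_train, freq_val, meta, alpha = 0.05) {
  common <- intersect(colnames(freq_train), colnames(freq_val))
  freq_train <- freq_train[, common, drop = FALSE]
  freq_val <- freq_val[, common, drop = FALSE]
  dirs <- assign_direction(freq_train, meta)
  grp_t <- meta$group[match(rownames(freq_train), meta$donor_id)]
  grp_v <- meta$group[match(rownames(freq_val), meta$donor_id)]
  res <- data.frame(cluster_id = common, direction = dirs$direction,
                    p_train_case = NA_real_, p_train_ctrl = NA_real_,
                    p_val_case = NA_real_, selected = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_along(common)) {
    g_low <- dirs$direction[j]
    if (is.na(g_low)) next
    g_other <- setdiff(.PATIENT_GROUPS, g_low)
    x_t <- freq_train[grp_t == g_low, j]
    y_t <- freq_train[grp_t == g_other, j]
    c_t <- freq_train[grp_t == "CTRL", j]
    x_v <- freq_val[grp_v == g_low, j]
    y_v <- freq_val[grp_v == g_other, j]
    p1 <- rank_sum_one_tailed(x_t, y_t, "less")
    p2 <- rank_sum_one_tailed(x_t, c_t, "less")
    p3 <- rank_sum_one_tailed(x_v, y_v, "less")
    res$p_train_case[j] <- p1
    res$p_train_ctrl[j] <- p2
    res$p_val_case[j] <- p3
    res$selected[j] <- nested_select(p1, p2, p3, alpha)
  }
  res
}

#' False-positive error-rate calculus of the nested design
#'
#' Analytic bookkeeping of the selection strategy: requiring one-tailed
#' significance at `alpha` in `n_tests_nested` independent comparisons gives
#' a per-cluster false-positive rate of `alpha^n_tests_nested`; a Bonferroni
#' correction over `n_comparisons` clusters instead would test each at
#' `alpha / n_comparisons`; combining both would give
#' `alpha^n_tests_nested / n_comparisons`. The "1 in N" reciprocals are
#' returned rounded as conventionally printed.
#'
#' @param alpha per-test significance level, in (0, 1).
#' @param n_tests_nested number of nested comparisons per cluster.
#' @param n_comparisons number of clusters tested.
#' @return list with `nested_rate`, `nested_one_in`, `bonferroni_alpha`,
#'   `bonferroni_one_in`, `combined_rate`, `combined_one_in`.
#' @export
error_rate_calculus <- function(alpha = 0.05, n_tests_nested = 3,
                                n_comparisons = 11) {
  .assert_scalar_prob(alpha, "alpha", open0 = TRUE, open1 = TRUE)
  stopifnot(n_tests_nested >= 1, n_comparisons >= 1)
  nested_rate <- alpha^n_tests_nested
  bonferroni_alpha <- alpha / n_comparisons
  combined_rate <- nested_rate / n_comparisons
  list(nested_rate = nested_rate,
       nested_one_in = round(1 / nested_rate),
       bonferroni_alpha = bonferroni_alpha,
       bonferroni_one_in = round(1 / bonferroni_alpha),
       combined_rate = combined_rate,
       combined_one_in = round(1 / combined_rate))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1; used for every
#' multiple-comparison family outside the nested selection (which, by
#' design, receives no additional adjustment).
#'
#' @param pvals vector of p-values in (0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  .assert_pvalues(pvals, "pvals")
  p.adjust(pvals, method = "BH")
}

#' Monte Carlo null selection rate of the nested rule
#'
#' Simulates donor-level frequencies i.i.d. from a continuous distribution
#' for the study's group sizes, fixes the one-tailed direction a priori, and
#' applies the nested three-test rule, returning the empirical per-cluster
#' selection proportion. The p-value computation is identical to
#' [rank_sum_one_tailed()] (there are no ties almost surely).
#'
#' With `share_cases = FALSE` (default) the three comparisons are drawn
#' independently, instantiating the independence model behind the
#' `alpha^3` error calculus of [error_rate_calculus()]. With
#' `share_cases = TRUE` the training case sample is reused in both training
#' comparisons, as in the actual study design; the induced positive
#' dependence inflates the joint rate several-fold above `alpha^3` (see the
#' package vignette).
#'
#' @param n_reps number of null replicates.
#' @param n_train donor counts `c(case, other, ctrl)` for the training
#'   cohort.
#' @param n_val donor counts `c(case, other)` for the validation cohort.
#' @param alpha per-test significance level.
#' @param seed integer seed.
#' @param share_cases reuse the training case sample across the two training
#'   comparisons (see Details).
#' @param chunk_size replicates simulated per block (memory control).
#' @return list with `rate`, `se` (binomial Monte Carlo standard error),
#'   `n_reps`, `n_selected`.
#' @export
null_selection_rate <- function(n_reps = 5e5,
                                n_train = c(case = 12, other = 16,
                                            ctrl = 20),
                                n_val = c(case = 8, other = 6),
                                alpha = 0.05, seed = 1,
                                share_cases = FALSE,
                                chunk_size = 50000L) {
  set.seed(seed)
  mE <- n_train[[1]]; mL <- n_train[[2]]; mC <- n_train[[3]]
  vE <- n_val[[1]]; vL <- n_val[[2]]
  # U = number of pairs with case value above the comparison value; a LOW
  # case sample gives small U, so the fixed "case-low" tail is P(U <= u).
  count_U <- function(X, Y) {
    U <- numeric(nrow(X))
    for (i in seq_len(ncol(X))) {
      for (j in seq_len(ncol(Y))) U <- U + (X[, i] > Y[, j])
    }
    U
  }
  n_sel <- 0
  done <- 0
  while (done < n_reps) {
    R <- min(chunk_size, n_reps - done)
    E <- matrix(runif(R * mE), R)
    L <- matrix(runif(R * mL), R)
    C <- matrix(runif(R * mC), R)
    E2 <- if (share_cases) E else matrix(runif(R * mE), R)
    Ev <- matrix(runif(R * vE), R)
    Lv <- matrix(runif(R * vL), R)
    p1 <- .p_less_from_U(count_U(E, L), mE, mL)
    p2 <- .p_less_from_U(count_U(E2, C), mE, mC)
    p3 <- .p_less_from_U(count_U(Ev, Lv), vE, vL)
    n_sel <- n_sel + sum(p1 < alpha & p2 < alpha & p3 < alpha)
    done <- done + R
  }
  rate <- n_sel / n_reps
  list(rate = rate,
       se = sqrt(rate * (1 - rate) / n_reps),
       n_reps = n_reps, n_selected = n_sel)
}
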