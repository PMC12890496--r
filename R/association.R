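## Blood-thymus paired correlations, hyperplasia-grade associations on log
## frequencies, and TCR repertoire contingency statistics.

#' Spearman correlation of paired blood and thymus frequencies
#'
#' Rank correlation with midranks. For small subcohorts (n <= 10) the
#' two-sided p-value is exact, by full enumeration of all rank
#' permutations; for larger n the usual t approximation is used.
#'
#' @param blood,thymus paired numeric vectors (percent of parent lineage);
#'   pairs with missing values are dropped.
#' @return list with `rho`, `p`, `n` and the p-value `method`.
#' @export
blood_thymus_spearman <- function(blood, thymus) {
  keep <- !is.na(blood) & !is.na(thymus)
  blood <- blood[keep]; thymus <- thymus[keep]
  n <- length(blood)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(blood) == 0 || sd(thymus) == 0) {
    stop("constant vector: Spearman correlation undefined")
  }
  rx <- rank(blood); ry <- rank(thymus)
  rho <- cor(rx, ry)
  if (n <= 10L) {
    p <- .spearman_perm_p(rx, ry)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- max(2 * pt(-abs(tstat), n - 2), .Machine$double.xmin)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Pearson correlation of log frequencies with ordinal hyperplasia grade
#'
#' Pearson's correlation is used instead of a rank correlation because rank
#' methods degrade when many grade values are identical. Frequencies are
#' log10-transformed with an offset (shared with the classification module);
#' the p-value is the two-sided t-test, adjusted by Benjamini-Hochberg
#' jointly with any sibling p-values from the same comparison family.
#'
#' @param freqs frequencies (percent of parent lineage).
#' @param grades ordinal grades coded as integers (e.g. 0-3).
#' @param sibling_pvals p-values of sibling tests in the same family.
#' @param log_offset offset added before log10.
#' @return list with `r`, `p`, `p_adjusted`, `n`.
#' @export
grade_pearson <- function(freqs, grades, sibling_pvals = numeric(0),
                          log_offset = 0.01) {
  keep <- !is.na(freqs) & !is.na(grades)
  freqs <- freqs[keep]; grades <- as.numeric(grades[keep])
  n <- length(freqs)
  if (n < 3L) stop("need at least 3 complete observations")
  lf <- log10(freqs + log_offset)
  if (sd(lf) == 0 || sd(grades) == 0) {
    stop("zero variance: Pearson correlation undefined")
  }
  r <- cor(lf, grades)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- max(2 * pt(-abs(tstat), n - 2), .Machine$double.xmin)
  p_adj <- bh_adjust(c(p, sibling_pvals))[1]
  list(r = r, p = p, p_adjusted = p_adj, n = n)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided p by hypergeometric enumeration and the conditional
#' maximum-likelihood odds ratio, as implemented in [stats::fisher.test()].
#' Family-wise Benjamini-Hochberg adjustment across a battery of repertoire
#' tests is applied by [repertoire_stats()].
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_enrichment <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (sum(table) == 0) stop("at least one positive margin required")
  ft <- fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Expanded-clone fraction (clonality)
#'
#' Fraction of the subset's cells whose clone — defined over the whole
#' repertoire table — contains at least 2 cells.
#'
#' @param repertoire repertoire table with `cell_id` and `clone_id`.
#' @param cells optional cell ids restricting the subset; defaults to all.
#' @return scalar fraction in [0, 1].
#' @export
clonality_fraction <- function(repertoire, cells = NULL) {
  if (anyNA(repertoire$clone_id)) stop("clone_id must be non-missing")
  sizes <- table(repertoire$clone_id)
  rows <- if (is.null(cells)) seq_len(nrow(repertoire))
          else which(repertoire$cell_id %in% cells)
  if (length(rows) == 0L) stop("empty subset")
  mean(sizes[repertoire$clone_id[rows]] >= 2)
}

#' Repertoire contingency statistics for cell subsets
#'
#' For each named subset of cells (e.g. the cells of a discriminant
#' cluster), compares against the rest of the repertoire: clonality
#' (expanded vs non-expanded cells), usage of selected TCR V-beta families,
#' and carriage of the invariant MAIT TCR-alpha pair (Va7.2 with Ja33).
#' All Fisher p-values of the battery are Benjamini-Hochberg adjusted
#' jointly.
#'
#' @param repertoire repertoire table (`cell_id`, `clone_id`, `v_alpha`,
#'   `j_alpha`, `v_beta_family`).
#' @param subsets named list of cell-id vectors.
#' @param vb_families V-beta families tested for differential usage.
#' @return data frame: subset, test, percentage inside and outside the
#'   subset, odds ratio, raw and adjusted p.
#' @export
repertoire_stats <- function(repertoire, subsets,
                             vb_families = c("Vb6", "Vb7")) {
  stopifnot(is.list(subsets), !is.null(names(subsets)))
  sizes <- table(repertoire$clone_id)
  clonal <- sizes[repertoire$clone_id] >= 2
  is_mait <- repertoire$v_alpha == "Va7.2" & repertoire$j_alpha == "Ja33"
  rows <- list()
  for (nm in names(subsets)) {
    inside <- repertoire$cell_id %in% subsets[[nm]]
    if (!any(inside)) stop("subset '", nm, "' matches no repertoire cells")
    add <- function(test, flag) {
      tab <- matrix(c(sum(flag & inside), sum(!flag & inside),
                      sum(flag & !inside), sum(!flag & !inside)), 2, 2)
      fe <- fisher_enrichment(tab)
      rows[[length(rows) + 1L]] <<- data.frame(
        subset = nm, test = test,
        pct_subset = 100 * mean(flag[inside]),
        pct_rest = 100 * mean(flag[!inside]),
        odds_ratio = fe$odds_ratio, p = fe$p,
        stringsAsFactors = FALSE)
    }
    add("clonality", clonal)
    for (vb in vb_families) {
      add(paste0(vb, " usage"), repertoire$v_beta_family == vb)
    }
    add("MAIT Va7.2/Ja33", is_mait)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p)
  out
}
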