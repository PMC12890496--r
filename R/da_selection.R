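## Supervised three-group differential-abundance cell selection:
## per-cell neighbourhood scoring, permutation-null thresholding, and
## subclustering of the selected cells.

# Per-cell donor-weighted neighbourhood composition matrix C (cells x
# donors): C[i, d] = w_d * (number of the cell's k neighbours from donor d),
# with w_d = 1 / donor cell count in the lineage. All group compositions --
# observed and donor-label-permuted -- are linear in C, which makes the
# permutation null cheap and exact over every cell.
.donor_composition <- function(D, w) {
  n <- nrow(D)
  C <- matrix(0, n, length(w))
  rows <- seq_len(n)
  for (j in seq_len(ncol(D))) {
    d <- D[, j]
    ix <- cbind(rows, d)
    C[ix] <- C[ix] + w[d]
  }
  C
}

# chi-square of the k-pseudo-count neighbourhood composition against the
# donor-balanced expectation; gcode maps donors to groups 1..3.
.chi2_scores <- function(C, gcode, e_prop, k) {
  o <- vapply(1:3, function(g) {
    cols <- which(gcode == g)
    if (length(cols) == 0L) numeric(nrow(C))
    else rowSums(C[, cols, drop = FALSE])
  }, numeric(nrow(C)))
  if (!is.matrix(o)) o <- matrix(o, nrow = nrow(C))
  s <- rowSums(o)
  e <- k * e_prop
  score <- numeric(nrow(C))
  for (g in 1:3) {
    score <- score + (k * o[, g] / s - e[g])^2 / e[g]
  }
  score
}

#' Score cells for three-group differential abundance
#'
#' For every cell of one cohort, the group composition of its k nearest
#' neighbours (within its lineage, in transformed marker space) is compared
#' with the donor-balanced expectation by a chi-square statistic. Each
#' neighbour is weighted by 1 / (its donor's cell count in the lineage) so
#' every donor contributes equally in expectation, and the expected
#' composition is proportional to the number of donors per group. Cells of
#' donors with an uncertain subgroup are excluded.
#'
#' The default neighbourhood size of 150 reflects that the planted signal of
#' the statistic grows linearly in k while its permutation null does not;
#' k = 150 comfortably separates even the weakest planted halving-sized effect from the null (see
#' the package vignette).
#'
#' @param cells cell table of a single cohort with lineage labels.
#' @param meta donor metadata with a `group` column.
#' @param k neighbourhood size; must be smaller than every scored lineage.
#' @param markers markers spanning the neighbourhood space.
#' @return object of class `da_scores`: `$scores` is a data frame with
#'   `cell_id`, `lineage` and non-negative `score`; per-lineage
#'   neighbourhood compositions are retained for permutation thresholding.
#' @export
score_cells_3group <- function(cells, meta, k = 150, markers = NULL) {
  if (length(unique(cells$cohort)) != 1L) {
    stop("cells must be restricted to one cohort")
  }
  grp <- meta$group[match(cells$donor_id, meta$donor_id)]
  if (anyNA(grp)) stop("every cell must have a donor present in meta")
  groups <- c("EOMG", "LOMG", "CTRL")
  include <- grp %in% groups
  donors_inc <- unique(cells$donor_id[include])
  dgroup <- meta$group[match(donors_inc, meta$donor_id)]
  for (g in groups) {
    if (!any(dgroup == g)) stop("group ", g, " has zero donors")
  }
  x_all <- marker_matrix(cells, markers)
  lin_present <- intersect(.LINEAGES, unique(cells$lineage))
  lineage_data <- list()
  score_parts <- list()
  for (lin in lin_present) {
    idx <- which(cells$lineage == lin & include)
    n <- length(idx)
    if (n == 0L) next
    if (k >= n) {
      stop("k (", k, ") must be smaller than the ", lin,
           " lineage size (", n, ")")
    }
    don <- factor(cells$donor_id[idx])
    dcode <- as.integer(don)
    dlev <- levels(don)
    w <- 1 / tabulate(dcode, nbins = length(dlev))
    gcode <- match(meta$group[match(dlev, meta$donor_id)], groups)
    e_prop <- tabulate(match(dgroup, groups), 3) / length(dgroup)
    nn <- .knn(x_all[idx, , drop = FALSE], k = k)
    C <- .donor_composition(matrix(dcode[nn$idx], n, k), w)
    sc <- .chi2_scores(C, gcode, e_prop, k)
    score_parts[[lin]] <- data.frame(cell_id = cells$cell_id[idx],
                                     lineage = lin, score = sc,
                                     stringsAsFactors = FALSE)
    lineage_data[[lin]] <- list(C = C, donors = dlev, e_prop = e_prop)
  }
  structure(list(scores = do.call(rbind, score_parts),
                 lineage_data = lineage_data, k = k,
                 donors = donors_inc,
                 donor_groups = dgroup, groups = groups),
            class = "da_scores")
}

#' Select candidate cells against a permutation null
#'
#' Per lineage, donor group labels are permuted across donors (preserving
#' group sizes) and the chi-square scores recomputed — for every cell, or
#' for a random subsample per permutation in very large lineages; the
#' pooled null scores define a data-driven threshold at the given quantile.
#' Cells scoring strictly above their lineage threshold are selected, so
#' the selected fraction is an output of the data, not an input.
#'
#' @param da a `da_scores` object from [score_cells_3group()].
#' @param quantile null quantile defining the threshold (default 0.9, i.e.
#'   about 10\% of cells selected under a global null).
#' @param n_perm number of donor-label permutations.
#' @param perm_cells cells scored per lineage per permutation; lineages
#'   with at most this many cells are scored in full.
#' @param seed integer seed for the permutations.
#' @return object of class `da_selection`: `$scores` gains a `selected`
#'   column; `$thresholds` reports per-lineage threshold and selected
#'   fraction.
#' @export
select_candidates <- function(da, quantile = 0.9, n_perm = 200,
                              perm_cells = 20000, seed = 1) {
  stopifnot(inherits(da, "da_scores"))
  set.seed(seed)
  groups <- da$groups
  dg <- setNames(da$donor_groups, da$donors)
  thresholds <- list()
  scores <- da$scores
  scores$selected <- FALSE
  perms <- lapply(seq_len(n_perm), function(p) setNames(sample(dg),
                                                        names(dg)))
  for (lin in names(da$lineage_data)) {
    ld <- da$lineage_data[[lin]]
    n <- nrow(ld$C)
    null_scores <- lapply(perms, function(gperm) {
      gcode_p <- match(gperm[ld$donors], groups)
      Ck <- if (n > perm_cells) {
        ld$C[sample.int(n, perm_cells), , drop = FALSE]
      } else ld$C
      .chi2_scores(Ck, gcode_p, ld$e_prop, da$k)
    })
    thr <- quantile(unlist(null_scores), quantile, names = FALSE)
    in_lin <- scores$lineage == lin
    sel <- in_lin & scores$score > thr
    scores$selected[sel] <- TRUE
    thresholds[[lin]] <- data.frame(
      lineage = lin, threshold = thr, n_cells = sum(in_lin),
      n_selected = sum(sel),
      frac_selected = sum(sel) / sum(in_lin),
      stringsAsFactors = FALSE)
  }
  structure(list(scores = scores,
                 thresholds = do.call(rbind, thresholds),
                 quantile = quantile, n_perm = n_perm),
            class = "da_selection")
}

# k-means++ seeding with the current RNG; returns k distinct rows of x.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 <= 0)) {
      i <- sample.int(n, 1)
    } else {
      i <- sample.int(n, 1, prob = pmax(d2, 0))
    }
    centers[j + 1L, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1L, ])^2))
  }
  unique(centers)
}

# two-stage clustering of one lineage: k-means overclustering followed by
# Ward merging of the (size-weighted) centres down to k_final clusters.
# The merge step keeps coherent subpopulations together that a single
# k-means pass at the final granularity would shatter.
.cluster_lineage <- function(x, k_final, overcluster) {
  n_distinct <- nrow(unique(x))
  k_final <- min(k_final, n_distinct)
  if (k_final == 1L) return(rep(1L, nrow(x)))
  k_over <- min(n_distinct, max(k_final * overcluster, k_final))
  centers <- .kmeanspp_centers(x, k_over)
  fit <- tryCatch(
    kmeans(x, centers = centers, iter.max = 100),
    error = function(e) kmeans(x, centers = centers, iter.max = 100,
                               algorithm = "MacQueen"))
  if (k_over == k_final) return(fit$cluster)
  hc <- hclust(dist(fit$centers)^2, method = "ward.D",
               members = fit$size)
  merge_map <- cutree(hc, k = k_final)
  merged <- merge_map[fit$cluster]
  as.integer(factor(merged, levels = unique(merged)))
}

#' Subcluster the selected cells into a candidate-cluster catalog
#'
#' Selected cells are partitioned per lineage by two-stage clustering:
#' k-means (k-means++ seeding, fixed seed) into an overclustered partition,
#' whose size-weighted centres are then merged by Ward's criterion down to
#' the lineage's share of the total cluster budget — the metaclustering
#' pattern standard in cytometry, which keeps coherent subpopulations
#' together. The budget is allocated across lineages proportionally to
#' their selected-cell counts (at least one cluster per non-empty lineage);
#' clusters are numbered globally in lineage order, e.g. `NK#49`. Centroids
#' are recorded on the common-marker subspace used for cross-cohort
#' transfer.
#'
#' @param cells the cohort's cell table (the one that was scored).
#' @param selection a `da_selection` from [select_candidates()].
#' @param budget total number of subclusters across lineages.
#' @param seed integer seed controlling the clustering initialization.
#' @param markers markers used for clustering; defaults to all.
#' @param common_markers markers on which centroids are recorded; defaults
#'   to `markers`.
#' @param overcluster overclustering factor of the first stage.
#' @return object of class `cluster_catalog` with elements `clusters`
#'   (cluster_id, lineage, n_cells_train), `centroids`, `donor_counts`
#'   (clusters x donors) and `assignments` (cell-level membership).
#' @export
subcluster_selected <- function(cells, selection, budget = 61, seed = 1,
                                markers = NULL, common_markers = NULL,
                                overcluster = 3) {
  stopifnot(inherits(selection, "da_selection"))
  if (budget <= 0) stop("budget must be a positive integer")
  sel_ids <- selection$scores$cell_id[selection$scores$selected]
  sub <- cells[cells$cell_id %in% sel_ids, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no selected cells to cluster")
  if (is.null(markers)) markers <- marker_cols(cells)
  if (is.null(common_markers)) common_markers <- markers
  lins <- intersect(.LINEAGES, unique(sub$lineage))
  n_l <- vapply(lins, function(l) sum(sub$lineage == l), 0L)
  # largest-remainder allocation of the budget, >= 1 per non-empty lineage
  raw <- budget * n_l / sum(n_l)
  k_l <- pmax(1L, floor(raw))
  left <- budget - sum(k_l)
  if (left > 0L) {
    extra <- order(raw - floor(raw), decreasing = TRUE)
    extra <- extra[seq_len(min(left, length(extra)))]
    k_l[extra] <- k_l[extra] + 1L
  }
  k_l <- pmin(k_l, n_l)
  set.seed(seed)
  assignments <- list()
  clusters <- list()
  centroids <- list()
  gid <- 0L
  for (li in seq_along(lins)) {
    lin <- lins[li]
    rows <- which(sub$lineage == lin)
    x <- marker_matrix(sub[rows, , drop = FALSE], markers)
    cl <- .cluster_lineage(x, k_l[li], overcluster)
    ids <- sprintf("%s#%d", lin, gid + seq_len(max(cl)))
    gid <- gid + max(cl)
    assignments[[lin]] <- data.frame(
      cell_id = sub$cell_id[rows], donor_id = sub$donor_id[rows],
      lineage = lin, cluster_id = ids[cl], stringsAsFactors = FALSE)
    xc <- marker_matrix(sub[rows, , drop = FALSE], common_markers)
    centroids[[lin]] <- do.call(rbind, lapply(seq_len(max(cl)), function(j) {
      colMeans(xc[cl == j, , drop = FALSE])
    }))
    rownames(centroids[[lin]]) <- ids
    clusters[[lin]] <- data.frame(
      cluster_id = ids, lineage = lin,
      n_cells_train = as.vector(table(factor(cl, seq_len(max(cl))))),
      stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, assignments)
  rownames(assignments) <- NULL
  clusters <- do.call(rbind, clusters)
  rownames(clusters) <- NULL
  donors <- sort(unique(cells$donor_id))
  donor_counts <- table(factor(assignments$cluster_id,
                               levels = clusters$cluster_id),
                        factor(assignments$donor_id, levels = donors))
  donor_counts <- matrix(as.integer(donor_counts), nrow(clusters),
                         length(donors),
                         dimnames = list(clusters$cluster_id, donors))
  structure(list(clusters = clusters,
                 centroids = do.call(rbind, centroids),
                 donor_counts = donor_counts,
                 assignments = assignments,
                 markers = markers, common_markers = common_markers),
            class = "cluster_catalog")
}

#' @export
print.cluster_catalog <- function(x, ...) {
  cat("Candidate-cluster catalog:", nrow(x$clusters), "clusters over",
      length(unique(x$clusters$lineage)), "lineages;",
      sum(x$clusters$n_cells_train), "cells\n")
  print(table(x$clusters$lineage))
  invisible(x)
}
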