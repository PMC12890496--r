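## Cross-cohort projection and nearest-neighbour cluster label transfer in a
## Euclidean space of common markers, plus the >50-cell eligibility filter.

#' Build the common-marker Euclidean space
#'
#' The common space is spanned by the intersection of the two cohorts'
#' panels; each marker is standardized by its training-cohort median and
#' robust standard deviation (MAD), and both cohorts are projected with the
#' SAME training parameters before any distance computation.
#'
#' @param panel_train,panel_val marker name vectors of the two cohorts.
#' @param cells_train training cohort cell table (used to estimate
#'   location/scale).
#' @return object of class `common_space` with `markers`, `center`, `scale`.
#' @export
build_common_space <- function(panel_train, panel_val, cells_train) {
  if (length(panel_train) == 0L || length(panel_val) == 0L) {
    stop("panels must be non-empty")
  }
  markers <- intersect(panel_train, panel_val)
  if (length(markers) == 0L) stop("marker panels share no markers")
  x <- marker_matrix(cells_train, markers)
  center <- apply(x, 2, median)
  scale <- apply(x, 2, mad)
  fallback <- scale <= 0
  if (any(fallback)) scale[fallback] <- apply(x[, fallback, drop = FALSE],
                                              2, sd)
  if (any(scale <= 0)) {
    stop("zero-variance marker(s) in the training cohort: ",
         paste(markers[scale <= 0], collapse = ", "))
  }
  structure(list(markers = markers, center = center, scale = scale),
            class = "common_space")
}

# project cells into the standardized common space
.common_coords <- function(cells, space) {
  missing <- setdiff(space$markers, names(cells))
  if (length(missing) > 0L) {
    stop("cells lack common-space marker(s): ",
         paste(missing, collapse = ", "))
  }
  x <- marker_matrix(cells, space$markers)
  scale(x, center = space$center, scale = space$scale)
}

#' Transfer training cluster labels to validation cells
#'
#' Each validation cell in a lineage that holds at least one candidate
#' cluster is assigned the cluster of its nearest selected training cell
#' (1-NN against the cells, not the centroids) in the standardized common
#' space. A cell exactly equidistant to training cells of different clusters
#' takes the lower cluster id. Cells farther than a distance gate — the
#' 99th percentile of within-cluster training 1-NN distances of the
#' assigned cluster — stay unassigned, preventing forced assignment of
#' out-of-manifold cells.
#'
#' @param catalog a `cluster_catalog` from [subcluster_selected()].
#' @param cells_train the training cohort cell table the catalog was built
#'   from.
#' @param cells_val validation cohort cell table (lineage-gated).
#' @param space a `common_space` from [build_common_space()].
#' @param gate_quantile quantile of within-cluster 1-NN distances used as
#'   the distance gate; `Inf` quantile = 1 disables gating in effect.
#' @return object of class `transfer_result` with `assignments` (per
#'   validation cell: cluster or NA, distance) and `counts` (clusters x
#'   validation donors).
#' @export
transfer_labels <- function(catalog, cells_train, cells_val, space,
                            gate_quantile = 0.99) {
  stopifnot(inherits(catalog, "cluster_catalog"),
            inherits(space, "common_space"))
  ref <- cells_train[match(catalog$assignments$cell_id,
                           cells_train$cell_id), , drop = FALSE]
  if (anyNA(ref$cell_id)) {
    stop("catalog cells not found in cells_train")
  }
  ref_z <- .common_coords(ref, space)
  ref_cluster <- catalog$assignments$cluster_id
  cluster_order <- catalog$clusters$cluster_id  # defines "lower cluster_id"
  val_donors <- sort(unique(cells_val$donor_id))
  assignments <- data.frame(cell_id = cells_val$cell_id,
                            donor_id = cells_val$donor_id,
                            lineage = cells_val$lineage,
                            cluster_id = NA_character_,
                            distance = NA_real_,
                            stringsAsFactors = FALSE)
  thresholds <- setNames(rep(NA_real_, length(cluster_order)), cluster_order)
  for (lin in unique(catalog$clusters$lineage)) {
    rrows <- which(catalog$assignments$lineage == lin)
    vrows <- which(cells_val$lineage == lin)
    # distance gate: within-cluster nearest-neighbour distances
    lin_within <- list()
    for (cl in catalog$clusters$cluster_id[catalog$clusters$lineage == lin]) {
      crows <- rrows[ref_cluster[rrows] == cl]
      if (length(crows) >= 2L) {
        d <- .knn(ref_z[crows, , drop = FALSE], k = 1L)$dist[, 1]
        lin_within[[cl]] <- d
        thresholds[cl] <- quantile(d, gate_quantile, names = FALSE)
      }
    }
    pooled <- unlist(lin_within, use.names = FALSE)
    pool_thr <- if (length(pooled)) quantile(pooled, gate_quantile,
                                             names = FALSE) else Inf
    singletons <- is.na(thresholds) &
      names(thresholds) %in% catalog$clusters$cluster_id[
        catalog$clusters$lineage == lin]
    thresholds[singletons] <- pool_thr
    if (length(vrows) == 0L) next
    val_z <- .common_coords(cells_val[vrows, , drop = FALSE], space)
    kq <- min(8L, length(rrows))
    nn <- .knn(ref_z[rrows, , drop = FALSE], query = val_z, k = kq)
    d1 <- nn$dist[, 1]
    assigned <- ref_cluster[rrows[nn$idx[, 1]]]
    has_tie <- which(rowSums(nn$dist - d1 <= 1e-9) > 1L)
    for (i in has_tie) {
      tied <- which(nn$dist[i, ] - d1[i] <= 1e-9)
      cls <- ref_cluster[rrows[nn$idx[i, tied]]]
      assigned[i] <- cls[which.min(match(cls, cluster_order))]
    }
    ok <- d1 <= thresholds[assigned]
    assignments$cluster_id[vrows[ok]] <- assigned[ok]
    assignments$distance[vrows] <- d1
  }
  counts <- table(factor(assignments$cluster_id, levels = cluster_order),
                  factor(assignments$donor_id, levels = val_donors))
  counts <- matrix(as.integer(counts), length(cluster_order),
                   length(val_donors),
                   dimnames = list(cluster_order, val_donors))
  structure(list(assignments = assignments, counts = counts,
                 thresholds = thresholds),
            class = "transfer_result")
}

#' Eligibility filter on transferred cluster counts
#'
#' A candidate cluster is eligible for statistical inference only if it was
#' recovered in the validation cohort in sufficient numbers: strictly more
#' than `min_cells` cells in total (so a cluster with exactly `min_cells`
#' cells fails).
#'
#' @param val_counts clusters x donors count matrix (from
#'   [transfer_labels()]`$counts`) or a named vector of totals.
#' @param min_cells strict lower bound on total validation cells.
#' @return character vector of eligible cluster ids.
#' @export
eligible_clusters <- function(val_counts, min_cells = 50) {
  if (min_cells < 0) stop("min_cells must be non-negative")
  totals <- if (is.matrix(val_counts)) rowSums(val_counts)
            else val_counts
  names(totals)[totals > min_cells]
}
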