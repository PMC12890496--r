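## Internal helpers shared across modules.

#' Marker columns of a cell table
#'
#' A cell table is a plain `data.frame` with one row per cell. Reserved
#' metadata columns are `cell_id`, `donor_id`, `cohort`, `tissue`, `lineage`,
#' `cluster` and `true_subpop`; every remaining column is interpreted as a
#' marker intensity on the transformed scale.
#'
#' @param cells cell table.
#' @return character vector of marker column names.
#' @export
marker_cols <- function(cells) {
  setdiff(names(cells), .META_COLS)
}

#' Marker intensity matrix of a cell table
#'
#' @param cells cell table.
#' @param markers markers to extract; defaults to all marker columns.
#' @return numeric matrix, cells x markers.
#' @export
marker_matrix <- function(cells, markers = NULL) {
  if (is.null(markers)) markers <- marker_cols(cells)
  missing <- setdiff(markers, names(cells))
  if (length(missing) > 0L) {
    stop("markers not present in cell table: ", paste(missing, collapse = ", "))
  }
  as.matrix(cells[, markers, drop = FALSE])
}

# k nearest neighbours of `query` among the rows of `data`. Self-queries
# exclude each point itself (by index, so duplicated coordinates return the
# twin, not the point). Exact search; the KMKNN algorithm handles the
# moderate dimensionality of cytometry panels far better than kd-trees.
.knn <- function(data, query = NULL, k, self = is.null(query)) {
  data <- as.matrix(data)
  param <- BiocNeighbors::KmknnParam()
  if (self) {
    res <- BiocNeighbors::findKNN(data, k = min(k, nrow(data) - 1L),
                                  BNPARAM = param, warn.ties = FALSE)
  } else {
    res <- BiocNeighbors::queryKNN(data, as.matrix(query),
                                   k = min(k, nrow(data)),
                                   BNPARAM = param, warn.ties = FALSE)
  }
  list(idx = res$index, dist = res$distance)
}

.assert_scalar_prob <- function(x, name, open0 = FALSE, open1 = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < 0 || x > 1 || (open0 && x == 0) || (open1 && x == 1)) {
    stop("'", name, "' must be a probability in ",
         if (open0) "(" else "[", "0,1", if (open1) ")" else "]")
  }
  invisible(x)
}

.assert_pvalues <- function(p, name = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("'", name, "' must contain p-values in (0, 1]")
  }
  invisible(p)
}
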