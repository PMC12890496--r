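## Lineage gating: arcsinh preprocessing, ordered threshold-gate rules, and
## Euclidean neighbor-enhanced label smoothing.

#' Arcsinh transform of raw intensities
#'
#' Standard cytometry preprocessing `asinh(x / cofactor)`; strictly
#' monotone, maps 0 to 0 and compresses the high end.
#'
#' @param x numeric vector (or matrix) of raw intensities.
#' @param cofactor positive scaling cofactor; the fluorescence-scale
#'   convention of 3000 is the default.
#' @return transformed values, same shape as `x`.
#' @export
arcsinh_transform <- function(x, cofactor = 3000) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0) {
    stop("cofactor must be a positive number")
  }
  asinh(x / cofactor)
}

#' Threshold-gate configuration
#'
#' An ordered list of rules; each rule names a lineage and a conjunction of
#' `marker: high` / `marker: low` conditions relative to a threshold on the
#' transformed scale. Cells are labeled by the first rule whose conditions
#' they all satisfy; cells matching no rule stay `unassigned`.
#'
#' @param rules list of rules; each rule is a list with elements `lineage`,
#'   `all_of` (named list/vector of `"high"`/`"low"`) and optionally
#'   `threshold` overriding the config default.
#' @param cofactor default arcsinh cofactor recorded with the config.
#' @param default_threshold gate threshold on the transformed scale.
#' @return object of class `gate_config`.
#' @export
gate_config <- function(rules, cofactor = 3000, default_threshold = 1.65) {
  stopifnot(is.list(rules), length(rules) > 0L)
  for (r in rules) {
    if (is.null(r$lineage) || is.null(r$all_of)) {
      stop("each rule needs 'lineage' and 'all_of'")
    }
    if (!all(unlist(r$all_of) %in% c("high", "low"))) {
      stop("rule conditions must be 'high' or 'low'")
    }
  }
  structure(list(rules = rules, cofactor = cofactor,
                 default_threshold = default_threshold),
            class = "gate_config")
}

#' Default gating rules for the synthetic panels
#'
#' Builds the conventional main-lineage gate hierarchy (gdT before the alpha
#' beta T subsets, then B, NK, ILC) restricted to the markers actually
#' present in `markers`; rules requiring absent markers are dropped, so a
#' reduced validation panel simply cannot reach the lineages it cannot see.
#'
#' @param markers character vector of available markers.
#' @param threshold gate threshold on the transformed scale.
#' @return a [gate_config].
#' @export
default_gate_config <- function(markers, threshold = 1.65) {
  all_rules <- list(
    list(lineage = "gdT", all_of = c(CD3 = "high", TCRgd = "high")),
    list(lineage = "CD4T", all_of = c(CD3 = "high", CD4 = "high",
                                      CD8 = "low")),
    list(lineage = "CD8T", all_of = c(CD3 = "high", CD8 = "high",
                                      CD4 = "low")),
    list(lineage = "B", all_of = c(CD3 = "low", CD19 = "high")),
    list(lineage = "NK", all_of = c(CD3 = "low", CD19 = "low",
                                    CD56 = "high")),
    list(lineage = "ILC", all_of = c(CD3 = "low", CD19 = "low",
                                     CD56 = "low", CD127 = "high"))
  )
  keep <- vapply(all_rules,
                 function(r) all(names(r$all_of) %in% markers), TRUE)
  gate_config(all_rules[keep], default_threshold = threshold)
}

#' Read a gate configuration from YAML
#'
#' @param path YAML file with fields `cofactor`, `default_threshold` and
#'   `rules` (a list of `lineage` / `all_of` mappings).
#' @return a [gate_config].
#' @export
read_gate_config <- function(path) {
  y <- yaml::read_yaml(path)
  rules <- lapply(y$rules, function(r) {
    r$all_of <- unlist(r$all_of)
    r
  })
  gate_config(rules,
              cofactor = if (is.null(y$cofactor)) 3000 else y$cofactor,
              default_threshold = if (is.null(y$default_threshold)) 1.65
                                  else y$default_threshold)
}

#' Assign main lineages by ordered threshold gates
#'
#' @param cells cell table on the transformed scale.
#' @param config a [gate_config].
#' @return the cell table with its `lineage` column replaced; cells matching
#'   no rule are `unassigned`.
#' @export
assign_lineages <- function(cells, config) {
  stopifnot(inherits(config, "gate_config"))
  if (isFALSE(attr(cells, "transformed"))) {
    stop("cells must be arcsinh-transformed before gating")
  }
  lineage <- rep("unassigned", nrow(cells))
  for (r in config$rules) {
    mk <- names(r$all_of)
    missing <- setdiff(mk, names(cells))
    if (length(missing) > 0L) {
      stop("gate rule for ", r$lineage, " references missing marker(s): ",
           paste(missing, collapse = ", "))
    }
    thr <- if (is.null(r$threshold)) config$default_threshold else r$threshold
    cond <- rep(TRUE, nrow(cells))
    for (m in mk) {
      cond <- cond & (if (r$all_of[[m]] == "high") cells[[m]] > thr
                      else cells[[m]] <= thr)
    }
    lineage[lineage == "unassigned" & cond] <- r$lineage
  }
  cells$lineage <- lineage
  cells
}

#' Euclidean neighbor-enhanced label smoothing
#'
#' One pass of majority voting: each cell's lineage label is replaced by the
#' majority label among its k Euclidean nearest neighbours in transformed
#' marker space; ties (including the original label) keep the original
#' label, making the operation conservative. Idempotent on
#' label-homogeneous data.
#'
#' @param cells cell table with lineage labels assigned.
#' @param k number of neighbours (positive, less than the number of cells).
#' @param markers markers spanning the smoothing space; defaults to all.
#' @return the cell table with smoothed `lineage` labels.
#' @export
neighbor_smooth_labels <- function(cells, k = 20, markers = NULL) {
  if (!is.numeric(k) || k <= 0) stop("k must be a positive integer")
  k <- as.integer(k)
  if (k >= nrow(cells)) stop("k must be smaller than the number of cells")
  x <- marker_matrix(cells, markers)
  nn <- .knn(x, k = k)
  labs <- cells$lineage
  ulab <- unique(labs)
  code <- match(labs, ulab)
  nbr <- matrix(code[nn$idx], nrow(x), k)
  counts <- matrix(0L, nrow(x), length(ulab))
  for (l in seq_along(ulab)) counts[, l] <- rowSums(nbr == l)
  top <- max.col(counts, ties.method = "first")
  topn <- counts[cbind(seq_len(nrow(counts)), top)]
  n_top <- rowSums(counts == topn)  # >1 => tied majority
  new <- ifelse(n_top == 1L, ulab[top], labs)
  cells$lineage <- new
  cells
}
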