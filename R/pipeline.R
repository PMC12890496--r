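## End-to-end discovery-and-validation pipeline on a synthetic study:
## gate -> smooth -> score -> select -> subcluster -> transfer -> nested
## tests -> PLS-DA classification.

#' Run the full endophenotype discovery pipeline on a synthetic study
#'
#' Generates a study from `spec`, re-derives lineages by threshold gating
#' with neighbor-enhanced smoothing (per cohort and tissue), scores and
#' selects candidate cells in the discovery cohort blood compartment,
#' subclusters them, transfers the cluster labels to the validation cohort
#' in the common-marker space, applies the >`min_cells` eligibility filter,
#' runs the nested directional tests, and (when at least one cluster is
#' selected) fits the PLS-DA classifier on the training cohort and applies
#' it unchanged to the validation cohort.
#'
#' @param spec a [synthetic_spec].
#' @param k_smooth neighbours for label smoothing.
#' @param k_da neighbourhood size for differential-abundance scoring.
#' @param da_quantile permutation-null quantile for candidate selection.
#' @param n_perm donor-label permutations per lineage.
#' @param perm_cells cells scored per permutation.
#' @param budget total subcluster budget.
#' @param min_cells strict validation-cell eligibility bound.
#' @param alpha per-test significance level of the nested rule.
#' @param classify fit and apply the PLS-DA when possible.
#' @param smooth apply one pass of neighbor-enhanced label smoothing after
#'   threshold gating (the full gating enhancement); disable for plain
#'   threshold gating.
#' @return list with the generated data and every intermediate result:
#'   `study`, `selection`, `catalog`, `space`, `transfer`, `eligible`,
#'   `freq_train`, `freq_val`, `nested`, and (if applicable) `model`,
#'   `classified_train`, `classified_val`, `confusion_train`,
#'   `confusion_val`.
#' @export
run_endotype_pipeline <- function(spec, k_smooth = 20, k_da = 150,
                                  da_quantile = 0.9, n_perm = 100,
                                  perm_cells = 2000, budget = 61,
                                  min_cells = 50, alpha = 0.05,
                                  classify = TRUE, smooth = TRUE) {
  study <- generate_study(spec)
  meta <- study$meta
  panels <- spec$marker_panels
  gate_and_smooth <- function(cells, panel) {
    cfg <- default_gate_config(panel)
    parts <- split(cells, paste(cells$cohort, cells$tissue))
    parts <- lapply(parts, function(p) {
      p <- assign_lineages(p, cfg)
      if (smooth) p <- neighbor_smooth_labels(p, k = k_smooth)
      p
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  }
  train <- gate_and_smooth(study$train, panels$train)
  val <- gate_and_smooth(study$val, panels$val)
  blood <- train[train$tissue == "blood", , drop = FALSE]

  da <- score_cells_3group(blood, meta, k = k_da)
  selection <- select_candidates(da, quantile = da_quantile,
                                 n_perm = n_perm, perm_cells = perm_cells,
                                 seed = spec$seed)
  common <- intersect(panels$train, panels$val)
  catalog <- subcluster_selected(blood, selection, budget = budget,
                                 seed = spec$seed,
                                 common_markers = common)
  space <- build_common_space(panels$train, panels$val, blood)
  transfer <- transfer_labels(catalog, blood, val, space)
  eligible <- eligible_clusters(transfer$counts, min_cells)

  freq_train <- cluster_frequencies(blood, catalog)
  freq_val <- cluster_frequencies(val, catalog,
                                  assignments = transfer$assignments)
  nested <- if (length(eligible) > 0L) {
    nested_test_clusters(freq_train[, eligible, drop = FALSE],
                         freq_val[, eligible, drop = FALSE],
                         meta, alpha = alpha)
  } else {
    data.frame(cluster_id = character(0), direction = character(0),
               p_train_case = numeric(0), p_train_ctrl = numeric(0),
               p_val_case = numeric(0), selected = logical(0))
  }
  out <- list(study = list(train = train, val = val, meta = meta),
              selection = selection, catalog = catalog, space = space,
              transfer = transfer, eligible = eligible,
              freq_train = freq_train, freq_val = freq_val,
              nested = nested)
  sel_cl <- nested$cluster_id[nested$selected]
  if (classify && length(sel_cl) > 0L) {
    labels_t <- setNames(meta$group, meta$donor_id)
    ft <- freq_train[, sel_cl, drop = FALSE]
    model <- tryCatch(fit_plsda(ft, labels_t), error = function(e) NULL)
    if (!is.null(model)) {
      out$model <- model
      out$classified_train <- classify_samples(model, freq_train)
      out$classified_val <- classify_samples(model, freq_val)
      truth <- setNames(meta$group, meta$donor_id)
      ct <- out$classified_train
      ct <- ct[truth[ct$donor_id] %in% c("EOMG", "LOMG") &
                 !is.na(ct$label), ]
      out$confusion_train <- confusion_stats(ct$label, truth[ct$donor_id])
      cv <- out$classified_val
      cv <- cv[truth[cv$donor_id] %in% c("EOMG", "LOMG") &
                 !is.na(cv$label), ]
      if (nrow(cv) > 0L) {
        out$confusion_val <- confusion_stats(cv$label, truth[cv$donor_id])
      }
    }
  }
  out
}

#' Match catalog clusters to planted subpopulations
#'
#' For every planted template, computes the Jaccard overlap (on cell
#' membership, over all discovery blood cells of the template's lineage)
#' between the template's cells and every catalog cluster of that lineage,
#' and reports the best-matching cluster. When nested test results are
#' supplied, a template counts as recovered if some SELECTED cluster
#' overlaps it with Jaccard >= `jaccard_min`.
#'
#' @param result a pipeline result from [run_endotype_pipeline()], or a list
#'   with elements `catalog` and `study`.
#' @param nested optional nested test results (defaults to
#'   `result$nested`).
#' @param jaccard_min overlap required to call a template recovered.
#' @return data frame: template, best cluster, its Jaccard, best SELECTED
#'   cluster and Jaccard, and the `recovered` flag.
#' @export
planted_recovery <- function(result, nested = result$nested,
                             jaccard_min = 0.5) {
  catalog <- result$catalog
  blood <- result$study$train
  blood <- blood[blood$tissue == "blood", , drop = FALSE]
  templates <- setdiff(unique(blood$true_subpop), "background")
  sel_cl <- if (!is.null(nested)) nested$cluster_id[nested$selected]
            else character(0)
  rows <- lapply(templates, function(tpl) {
    p_ids <- blood$cell_id[blood$true_subpop == tpl]
    lin <- blood$lineage[match(p_ids[1], blood$cell_id)]
    # lineage of the template per the catalog's view: use majority gated
    lin <- names(sort(table(blood$lineage[blood$true_subpop == tpl]),
                      decreasing = TRUE))[1]
    cls <- catalog$clusters$cluster_id[catalog$clusters$lineage == lin]
    if (length(cls) == 0L) {
      return(data.frame(template = tpl, best_cluster = NA_character_,
                        jaccard = 0, best_selected = NA_character_,
                        jaccard_selected = 0, recovered = FALSE,
                        stringsAsFactors = FALSE))
    }
    jac <- vapply(cls, function(cl) {
      c_ids <- catalog$assignments$cell_id[
        catalog$assignments$cluster_id == cl]
      length(intersect(p_ids, c_ids)) / length(union(p_ids, c_ids))
    }, 0)
    b <- which.max(jac)
    sel <- intersect(cls, sel_cl)
    js <- if (length(sel)) jac[sel] else 0
    bs <- if (length(sel)) sel[which.max(js)] else NA_character_
    data.frame(template = tpl, best_cluster = cls[b], jaccard = jac[b],
               best_selected = bs, jaccard_selected = max(js),
               recovered = max(js) >= jaccard_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
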