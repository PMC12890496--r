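## One-component PLS-DA on selected-cluster frequencies: training-fixed
## preprocessing, weights and threshold, transferred unchanged to every
## later cohort.

#' Fit a one-component PLS-DA on cluster frequencies
#'
#' Frequencies (percent of parent lineage) are log10-transformed with a
#' small offset, standardized by training statistics, and a single partial
#' least squares component is fit against +/-1 class coding (the
#' first-component weight vector is proportional to the covariance of each
#' standardized predictor with the centered class code). The score axis is
#' oriented so the mean EOMG score exceeds the mean LOMG score, and the
#' decision threshold is fixed at the midpoint of the training class mean
#' scores. All parameters are stored so later cohorts are projected without
#' any refitting.
#'
#' @param freq donors x clusters frequency matrix restricted to the selected
#'   clusters (training cohort).
#' @param labels character vector of class labels (`"EOMG"`/`"LOMG"`),
#'   either named by donor or aligned with `rownames(freq)`; donors with
#'   other labels or missing frequencies are dropped.
#' @param log_offset offset added before log10 (percentage scale).
#' @return object of class `plsda_model`: cluster ids, preprocessing
#'   parameters, unit-norm weight vector, threshold and training scores.
#' @export
fit_plsda <- function(freq, labels, log_offset = 0.01) {
  if (is.null(rownames(freq))) stop("freq must have donor rownames")
  if (!is.null(names(labels))) labels <- labels[rownames(freq)]
  keep <- labels %in% c("EOMG", "LOMG") & complete.cases(freq)
  freq <- freq[keep, , drop = FALSE]
  labels <- labels[keep]
  if (sum(labels == "EOMG") < 2L || sum(labels == "LOMG") < 2L) {
    stop("need at least 2 donors per class")
  }
  x <- log10(freq + log_offset)
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  if (any(scl == 0)) {
    stop("constant predictor column(s): ",
         paste(colnames(freq)[scl == 0], collapse = ", "))
  }
  xs <- scale(x, center = center, scale = scl)
  y <- ifelse(labels == "EOMG", 1, -1)
  yc <- y - mean(y)
  w <- drop(crossprod(xs, yc))
  w <- w / sqrt(sum(w^2))
  scores <- drop(xs %*% w)
  if (mean(scores[labels == "EOMG"]) < mean(scores[labels == "LOMG"])) {
    w <- -w
    scores <- -scores
  }
  thr <- decision_threshold(scores, labels)
  structure(list(cluster_ids = colnames(freq),
                 log_offset = log_offset,
                 center = center, scale = scl,
                 weights = setNames(w, colnames(freq)),
                 threshold = thr,
                 train_scores = data.frame(donor_id = rownames(freq),
                                           score = scores, label = labels,
                                           stringsAsFactors = FALSE)),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("One-component PLS-DA over", length(x$cluster_ids), "clusters\n")
  infl <- influence_fractions(x)
  cat("  influence:",
      paste(sprintf("%s %.0f%%", names(infl), 100 * infl), collapse = ", "),
      "\n")
  cat("  threshold:", format(x$threshold, digits = 4),
      "(EOMG above, LOMG at or below)\n")
  invisible(x)
}

#' Influence fraction of each cluster on the discriminant vector
#'
#' `|w_i| / sum_j |w_j|` on the standardized scale; fractions sum to 1.
#'
#' @param model a `plsda_model`.
#' @return named numeric vector of fractions.
#' @export
influence_fractions <- function(model) {
  w <- model$weights
  if (all(w == 0)) stop("zero weight vector")
  abs(w) / sum(abs(w))
}

#' Midpoint decision threshold between class score means
#'
#' @param scores numeric discriminant scores.
#' @param labels class labels aligned with `scores`.
#' @param classes the two classes whose means are bisected.
#' @return scalar threshold.
#' @export
decision_threshold <- function(scores, labels,
                               classes = c("EOMG", "LOMG")) {
  m <- vapply(classes, function(cl) {
    v <- scores[labels == cl]
    if (length(v) == 0L) stop("class ", cl, " absent")
    mean(v)
  }, 0)
  unname(mean(m))
}

#' Project and classify donors with a fitted model
#'
#' Applies the model's stored preprocessing and weight vector; a donor is
#' labeled EOMG if its score is strictly above the stored threshold, LOMG
#' otherwise (a score exactly at the threshold is LOMG — the conservative
#' convention for thymectomy-directed use). Donors with any missing
#' frequency are reported unclassifiable (`NA`).
#'
#' @param model a `plsda_model`.
#' @param freq donors x clusters frequency matrix containing all model
#'   clusters.
#' @return data frame: `donor_id`, `score`, `label`.
#' @export
classify_samples <- function(model, freq) {
  missing <- setdiff(model$cluster_ids, colnames(freq))
  if (length(missing) > 0L) {
    stop("freq lacks model cluster(s): ", paste(missing, collapse = ", "))
  }
  freq <- freq[, model$cluster_ids, drop = FALSE]
  ok <- complete.cases(freq)
  scores <- rep(NA_real_, nrow(freq))
  if (any(ok)) {
    xs <- scale(log10(freq[ok, , drop = FALSE] + model$log_offset),
                center = model$center, scale = model$scale)
    scores[ok] <- drop(xs %*% model$weights)
  }
  data.frame(donor_id = rownames(freq),
             score = scores,
             label = ifelse(is.na(scores), NA_character_,
                            ifelse(scores > model$threshold, "EOMG",
                                   "LOMG")),
             stringsAsFactors = FALSE)
}

#' Confusion counts and rates
#'
#' @param pred,truth aligned label vectors (equal length; named vectors are
#'   aligned by name).
#' @param positive the positive class (sensitivity refers to it).
#' @return object of class `confusion_stats`: TP/FP/TN/FN counts,
#'   sensitivity, specificity and accuracy as proportions, plus the rounded
#'   percentages conventionally reported.
#' @export
confusion_stats <- function(pred, truth, positive = "EOMG") {
  if (!is.null(names(pred)) && !is.null(names(truth))) {
    if (!setequal(names(pred), names(truth))) {
      stop("pred and truth cover different donor sets")
    }
    truth <- truth[names(pred)]
  } else if (length(pred) != length(truth)) {
    stop("pred and truth must be aligned")
  }
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  tn <- sum(pred != positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / (tp + fp + tn + fn)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 sensitivity_pct = round(100 * sens),
                 specificity_pct = round(100 * spec),
                 accuracy_pct = round(100 * acc)),
            class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("sensitivity %d%%  specificity %d%%  accuracy %d%%\n",
              x$sensitivity_pct, x$specificity_pct, x$accuracy_pct))
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' Standard threshold sweep over the unique score values (ties grouped),
#' with the area computed by the trapezoid rule; equals the Mann-Whitney
#' U / (n1 n2) probability that a random positive scores above a random
#' negative (ties counted half).
#'
#' @param scores numeric discriminant scores.
#' @param labels class labels aligned with `scores`.
#' @param positive the positive class.
#' @return list with `points` (threshold, fpr, tpr) and `auc`.
#' @export
roc_points <- function(scores, labels, positive = "EOMG") {
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), 0)
  points <- data.frame(threshold = c(Inf, thr),
                       fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) *
               (head(points$tpr, -1) + points$tpr[-1]) / 2)
  list(points = points, auc = auc)
}

#' Serialize / restore a PLS-DA model as JSON
#'
#' @param model a `plsda_model`.
#' @param path JSON file path.
#' @return `read_plsda` returns the restored `plsda_model`.
#' @export
write_plsda <- function(model, path) {
  out <- list(cluster_ids = model$cluster_ids,
              log_offset = model$log_offset,
              center = as.list(model$center),
              scale = as.list(model$scale),
              weights = as.list(model$weights),
              threshold = model$threshold)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plsda
#' @export
read_plsda <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(cluster_ids = j$cluster_ids,
                 log_offset = j$log_offset,
                 center = unlist(j$center), scale = unlist(j$scale),
                 weights = unlist(j$weights), threshold = j$threshold,
                 train_scores = NULL),
            class = "plsda_model")
}
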