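#' Bagged decision-tree ensemble specification
#'
#' Defaults follow the published configuration: 2,000 trees, Gini split
#' quality, maximum depth 10, bootstrap resampling, decision threshold 0.5
#' (strictly greater than 0.5 is called pathogenic).
#'
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth.
#' @param threshold decision threshold on the score.
#' @param score_rule `"probability"` (mean per-tree class probability,
#'   default) or `"vote"` (fraction of trees voting pathogenic).
#' @param seed integer seed making training deterministic.
#' @return list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_trees = 2000, max_depth = 10, threshold = 0.5,
                          score_rule = c("probability", "vote"),
                          seed = 1L) {
  score_rule <- match.arg(score_rule)
  if (n_trees < 1 || max_depth < 1) stop("n_trees and max_depth must be >= 1")
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 threshold = threshold, score_rule = score_rule,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Drop rows with missing predictor scores
#'
#' Rows with any missing value in the requested feature columns are removed
#' before training and evaluation; the number dropped is reported via
#' `message()` (mirroring evaluation restricted to variants for which all
#' scores are available).
#'
#' @param data scored-variant data frame.
#' @param features predictor column names.
#' @return the complete-case subset.
#' @export
drop_incomplete_scores <- function(data, features) {
  keep <- stats::complete.cases(data[, features, drop = FALSE])
  if (any(!keep)) {
    message(sum(!keep), " row(s) dropped for missing scores (",
            sum(keep), " retained)")
  }
  data[keep, , drop = FALSE]
}

#' Train the ensemble classifier
#'
#' A bagged forest of depth-bounded Gini decision trees ([ranger::ranger()]
#' with bootstrap resampling), deterministic under the spec seed.
#'
#' @param data data frame with the predictor columns and a `label` column
#'   (`pathogenic` vs `benign`, or any two labels with `pathogenic` one of
#'   them).
#' @param features predictor column names.
#' @param spec an [ensemble_spec()].
#' @return list of class `ensemble_model` with the fitted forest, the
#'   feature set and the spec.
#' @export
train_ensemble <- function(data, features, spec = ensemble_spec()) {
  missing <- setdiff(features, names(data))
  if (length(missing)) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  }
  data <- drop_incomplete_scores(data, features)
  lab <- factor(data$label)
  if (nlevels(lab) < 2) stop("training set must contain both classes")
  if (!"pathogenic" %in% levels(lab)) {
    stop("one training label must be 'pathogenic'")
  }
  df <- data[, features, drop = FALSE]
  df$.label <- lab
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = spec$n_trees, max.depth = spec$max_depth,
    splitrule = "gini",
    probability = spec$score_rule == "probability",
    replace = TRUE, seed = spec$seed, num.threads = 1
  )
  structure(list(fit = fit, features = features, spec = spec,
                 levels = levels(lab)),
            class = "ensemble_model")
}

#' Score and label new variants
#'
#' The score is the ensemble's probability of the pathogenic class: the
#' mean per-tree class probability under the `"probability"` rule, or the
#' fraction of trees voting pathogenic under `"vote"`. A score strictly
#' greater than the threshold is labelled `pathogenic`; at or below it,
#' `benign`.
#'
#' @param model an `ensemble_model`.
#' @param newdata data frame with the model's feature columns.
#' @return numeric scores in `[0, 1]`.
#' @rdname predict_ensemble
#' @export
predict_score <- function(model, newdata) {
  missing <- setdiff(model$features, names(newdata))
  if (length(missing)) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  }
  df <- newdata[, model$features, drop = FALSE]
  pr <- stats::predict(model$fit, data = df, num.threads = 1,
                       predict.all = model$spec$score_rule == "vote")
  if (model$spec$score_rule == "vote") {
    path_idx <- which(model$levels == "pathogenic")
    rowMeans(pr$predictions == path_idx)
  } else {
    pr$predictions[, "pathogenic"]
  }
}

#' @param score numeric score(s) in `[0, 1]`.
#' @param threshold decision threshold (strict `>` is pathogenic).
#' @rdname predict_ensemble
#' @export
predict_label <- function(score, threshold = 0.5) {
  ifelse(score > threshold, "pathogenic", "benign")
}

#' Confusion-matrix metric panel
#'
#' Standard confusion-derived metrics with `pathogenic` as the positive
#' class: sensitivity, specificity, balanced accuracy, MCC, F1, precision,
#' false positive and false negative rates, and the rank-based AUC (the
#' probability that a random pathogenic variant outranks a random benign
#' one, midranks under ties). An MCC denominator of zero yields 0 by
#' convention; with a single-class truth, the undefined entries are `NA`.
#'
#' @param labels true labels (`pathogenic` positive).
#' @param predicted predicted labels.
#' @param scores numeric scores for the AUC (optional; `NA` AUC if absent).
#' @return list of class `metrics_report`.
#' @export
compute_metrics <- function(labels, predicted, scores = NULL) {
  pos <- labels == "pathogenic"
  ppos <- predicted == "pathogenic"
  tp <- sum(pos & ppos); fn <- sum(pos & !ppos)
  tn <- sum(!pos & !ppos); fp <- sum(!pos & ppos)
  div <- function(n, d) if (d == 0) NA_real_ else n / d
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  f1 <- div(2 * tp, 2 * tp + fp + fn)
  auc <- if (!is.null(scores) && any(pos) && any(!pos)) {
    auc_rank(pos, scores)
  } else {
    NA_real_
  }
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = sens, specificity = spec,
         balanced_accuracy = mean(c(sens, spec)),
         mcc = mcc, f1 = f1, precision = prec,
         fpr = if (is.na(spec)) NA_real_ else 1 - spec,
         fnr = if (is.na(sens)) NA_real_ else 1 - sens,
         auc = auc),
    class = "metrics_report"
  )
}

# Rank-based AUC: P(score_path > score_benign) + 0.5 P(tie).
auc_rank <- function(pos, scores) {
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("sens %.3f  spec %.3f  bal.acc %.3f  MCC %.3f  ",
                     "F1 %.3f  prec %.3f  AUC %s\n"),
              x$sensitivity, x$specificity, x$balanced_accuracy, x$mcc,
              x$f1, x$precision,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' ROC curve points
#'
#' FPR/TPR at every distinct score threshold, sufficient to re-plot the
#' ROC curve.
#'
#' @param labels true labels (`pathogenic` positive).
#' @param scores numeric scores.
#' @return data frame `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(labels, scores) {
  pos <- labels == "pathogenic"
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(
    threshold = th,
    fpr = vapply(th, function(t) mean(scores[!pos] >= t), numeric(1)),
    tpr = vapply(th, function(t) mean(scores[pos] >= t), numeric(1))
  )
}

#' Compare ensembles with and without the structural index
#'
#' Trains three ensembles on a common train/test split — predictor scores
#' plus the class-context index, plus the all-genes index, and without any
#' index — and evaluates each on the identical test set.
#'
#' @param data scored-variant data frame with columns `sift`, `polyphen2`,
#'   `cadd`, `p3dfi_class`, `p3dfi_global`, `label`.
#' @param spec an [ensemble_spec()].
#' @param train_frac fraction of rows used for training.
#' @param split_seed seed for the split (defaults to the spec seed).
#' @return data frame with one row of metrics per model.
#' @export
compare_models <- function(data, spec = ensemble_spec(), train_frac = 0.5,
                           split_seed = spec$seed) {
  base <- c("sift", "polyphen2", "cadd")
  sets <- list(
    with_class_p3dfi = c(base, "p3dfi_class"),
    with_global_p3dfi = c(base, "p3dfi_global"),
    without_p3dfi = base
  )
  data <- drop_incomplete_scores(data, unique(unlist(sets)))
  n <- nrow(data)
  set.seed(split_seed)
  idx <- sample.int(n, floor(n * train_frac))
  train <- data[idx, , drop = FALSE]
  test <- data[-idx, , drop = FALSE]
  if (!nrow(test)) stop("empty test set")
  out <- lapply(names(sets), function(nm) {
    model <- train_ensemble(train, sets[[nm]], spec)
    sc <- predict_score(model, test)
    m <- compute_metrics(test$label, predict_label(sc, spec$threshold), sc)
    data.frame(model = nm, sensitivity = m$sensitivity,
               specificity = m$specificity,
               balanced_accuracy = m$balanced_accuracy, mcc = m$mcc,
               f1 = m$f1, precision = m$precision, fpr = m$fpr,
               fnr = m$fnr, auc = m$auc, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
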