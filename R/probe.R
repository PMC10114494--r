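# Linear probes: fit the Method-1 ridge mapping on a frozen representation
# to measure how much density signal the representation carries, and compare
# predictions across models.

#' Fit and evaluate a linear probe on a representation
#'
#' Appends a bias column to the representation and runs the same
#' subject-level cross-validated ridge mapping as Method 1, so differences
#' between models come only from their representations. Three label rules:
#' `Av` trains and tests on per-image averaged reader scores; `Ind1` trains
#' one mapping per reader on that reader's labels, tests each against the
#' averaged scores, and averages the metrics across readers (SD as
#' uncertainty); `Ind2` does the same but computes the metrics on the
#' concatenated prediction set with a bootstrap CI.
#'
#' @param rep n x feature_dim representation matrix (rownames = image ids).
#' @param labels Long label table (`image_id`, `reader_id`, `score`).
#' @param meta Cohort `meta` data frame (subject ids for fold planning).
#' @param label_rule `"Av"`, `"Ind1"` or `"Ind2"`.
#' @param lambda2 Ridge strength (shared across all probed models).
#' @param k CV folds.
#' @param seed Integer seed (fold plan, bootstrap).
#' @param n_boot Bootstrap repeats for CIs (0 disables).
#' @param min_images Readers with fewer images are excluded (recorded).
#' @return List with `rank_corr`, `rmse` (each `value`, `low`, `high` — for
#'   `Ind1` the half-width is the between-reader SD), `n`, `excluded`
#'   readers, and `predictions` (image ids, predictions and the labels they
#'   were scored against).
#' @export
probe_fit_eval <- function(rep, labels, meta,
                           label_rule = c("Av", "Ind1", "Ind2"),
                           lambda2 = 1, k = 5L, seed = 1L, n_boot = 0L,
                           min_images = 50L) {
  label_rule <- match.arg(label_rule)
  X <- cbind(rep, 1)
  av <- averaged_labels(labels)
  subj <- meta$subject_id[match(av$image_id, meta$image_id)]
  if (label_rule == "Av") {
    rows <- data.frame(image_id = av$image_id, subject_id = subj,
                       label = av$label, stringsAsFactors = FALSE)
    pred <- cv_ridge_predict(X, rows, k = k, lambda2 = lambda2, seed = seed)
    pv <- pred[rows$image_id]
    mr <- metric_row("Av", pv, rows$label, n_boot = n_boot, seed = seed)
    return(list(
      rank_corr = c(value = mr$rank_corr, low = mr$rank_corr_low,
                    high = mr$rank_corr_high),
      rmse = c(value = mr$rmse, low = mr$rmse_low, high = mr$rmse_high),
      n = mr$n, excluded = character(0),
      predictions = data.frame(image_id = rows$image_id, prediction = pv,
                               label = rows$label, stringsAsFactors = FALSE,
                               row.names = NULL)))
  }
  # Ind rules: per-reader mapping trained on that reader's scores, tested
  # against the averaged scores of the held-out images.
  readers <- sort(unique(labels$reader_id))
  per <- list(); preds <- list(); excluded <- character(0)
  av_of <- stats::setNames(av$label, av$image_id)
  for (r in readers) {
    sel <- labels$reader_id == r
    if (sum(sel) < min_images) { excluded <- c(excluded, r); next }
    rows <- data.frame(
      image_id = labels$image_id[sel],
      subject_id = meta$subject_id[match(labels$image_id[sel], meta$image_id)],
      label = labels$score[sel], stringsAsFactors = FALSE)
    pred <- cv_ridge_predict(X, rows, k = k, lambda2 = lambda2, seed = seed)
    pv <- pred[rows$image_id]
    yv <- av_of[rows$image_id]
    per[[r]] <- data.frame(reader = r, rank_corr = spearman(pv, yv),
                           rmse = rmse(pv, yv), n = length(pv),
                           stringsAsFactors = FALSE)
    preds[[r]] <- data.frame(image_id = rows$image_id, prediction = pv,
                             label = yv, stringsAsFactors = FALSE,
                             row.names = NULL)
  }
  if (!length(per)) stop("no reader met the probe inclusion threshold", call. = FALSE)
  per <- do.call(rbind, per)
  pooled <- do.call(rbind, preds)
  if (label_rule == "Ind1") {
    list(rank_corr = c(value = mean(per$rank_corr),
                       low = mean(per$rank_corr) - stats::sd(per$rank_corr),
                       high = mean(per$rank_corr) + stats::sd(per$rank_corr)),
         rmse = c(value = mean(per$rmse),
                  low = mean(per$rmse) - stats::sd(per$rmse),
                  high = mean(per$rmse) + stats::sd(per$rmse)),
         n = sum(per$n), excluded = excluded, per_reader = per,
         predictions = pooled)
  } else {
    mr <- metric_row("Ind2", pooled$prediction, pooled$label,
                     n_boot = n_boot, seed = seed)
    list(rank_corr = c(value = mr$rank_corr, low = mr$rank_corr_low,
                       high = mr$rank_corr_high),
         rmse = c(value = mr$rmse, low = mr$rmse_low, high = mr$rmse_high),
         n = mr$n, excluded = excluded, per_reader = per,
         predictions = pooled)
  }
}

#' Compare two prediction vectors
#'
#' Rank correlation and RMSE between aligned prediction vectors from two
#' models; both metrics are symmetric in their arguments.
#'
#' @param pred_a,pred_b Named numeric vectors over the same image ids.
#' @return List with `rank_corr` and `rmse`.
#' @export
compare_predictions <- function(pred_a, pred_b) {
  if (is.null(names(pred_a)) || is.null(names(pred_b))) {
    if (length(pred_a) != length(pred_b)) {
      stop("unnamed prediction vectors must have equal length", call. = FALSE)
    }
  } else {
    if (!setequal(names(pred_a), names(pred_b))) {
      stop("prediction vectors cover different image ids", call. = FALSE)
    }
    pred_b <- pred_b[names(pred_a)]
  }
  list(rank_corr = spearman(pred_a, pred_b), rmse = rmse(pred_a, pred_b))
}
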