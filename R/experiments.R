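# Method 1: subset experiments over the closed-form ridge mapping.

#' Subset experiment specification
#'
#' Describes which image/label subset a mapping experiment runs on:
#' `individual` (images scored by one reader, that reader's labels), `pair`
#' (images scored by the same two readers, averaged labels) or `all` (the
#' full table, with `label_rule` choosing averaged or individual labels).
#' Subsets smaller than `min_images` distinct images are excluded rather
#' than fitted, mirroring the reliability threshold applied to small reader
#' subsets.
#'
#' @param mode One of `"individual"`, `"pair"`, `"all"`.
#' @param reader_ids One reader id (`individual`) or two (`pair`).
#' @param min_images Inclusion threshold on distinct images (default 400 at
#'   desk scale; 4000 mirrors the source cohort's threshold).
#' @param label_rule `"individual"` or `"averaged"`; forced by `mode` except
#'   for `"all"`.
#' @return Object of class `subset_spec`.
#' @export
subset_spec <- function(mode = c("individual", "pair", "all"),
                        reader_ids = NULL, min_images = 400L,
                        label_rule = NULL) {
  mode <- match.arg(mode)
  if (mode == "individual") {
    if (length(reader_ids) != 1L) stop("individual mode needs one reader_id", call. = FALSE)
    label_rule <- "individual"
  } else if (mode == "pair") {
    if (length(reader_ids) != 2L) stop("pair mode needs two reader_ids", call. = FALSE)
    label_rule <- "averaged"
  } else {
    label_rule <- match.arg(label_rule, c("averaged", "individual"))
  }
  structure(list(mode = mode, reader_ids = reader_ids,
                 min_images = as.integer(min_images), label_rule = label_rule),
            class = "subset_spec")
}

# Per-image averaged labels from the long label table.
averaged_labels <- function(labels) {
  agg <- tapply(labels$score, labels$image_id, mean)
  data.frame(image_id = names(agg), label = as.numeric(agg),
             stringsAsFactors = FALSE)
}

# Training rows (image_id, subject_id, label) for a subset spec.
subset_rows <- function(labels, meta, spec) {
  sub2subj <- meta$subject_id[match(labels$image_id, meta$image_id)]
  if (spec$mode == "individual") {
    sel <- labels$reader_id == spec$reader_ids
    rows <- data.frame(image_id = labels$image_id[sel],
                       subject_id = sub2subj[sel],
                       label = labels$score[sel], stringsAsFactors = FALSE)
  } else if (spec$mode == "pair") {
    by_img <- split(seq_len(nrow(labels)), labels$image_id)
    keep <- vapply(by_img, function(i) setequal(labels$reader_id[i], spec$reader_ids),
                   logical(1))
    idx <- unlist(by_img[keep], use.names = FALSE)
    av <- tapply(labels$score[idx], labels$image_id[idx], mean)
    rows <- data.frame(image_id = names(av),
                       subject_id = meta$subject_id[match(names(av), meta$image_id)],
                       label = as.numeric(av), stringsAsFactors = FALSE)
  } else if (spec$label_rule == "averaged") {
    av <- averaged_labels(labels)
    rows <- data.frame(image_id = av$image_id,
                       subject_id = meta$subject_id[match(av$image_id, meta$image_id)],
                       label = av$label, stringsAsFactors = FALSE)
  } else {
    rows <- data.frame(image_id = labels$image_id, subject_id = sub2subj,
                       label = labels$score, stringsAsFactors = FALSE)
  }
  rows[order(rows$image_id), , drop = FALSE]
}

#' Run one subset mapping experiment
#'
#' Fits the ridge mapping with subject-level k-fold cross-validation on the
#' subset defined by `spec` and evaluates the held-out predictions against
#' the subset's labels (each (image, score) pair is a separate evaluation
#' row under individual labels). Subsets below the inclusion threshold
#' return an explicit exclusion record, never a silent skip.
#'
#' @param features Feature matrix from [extract_features()] (rownames are
#'   image ids).
#' @param labels Long label table from [assign_reader_pairs()].
#' @param meta Cohort `meta` data frame (for subject ids).
#' @param spec A [subset_spec()].
#' @param lambda2 Ridge strength.
#' @param k CV folds.
#' @param seed Integer seed (fold plan).
#' @param n_boot Bootstrap repeats for metric CIs (0 disables).
#' @return List: `excluded` flag (with `reason`, `n` when excluded) or
#'   `predictions` (data frame `image_id`, `prediction`, `label`) and
#'   `metrics` (one-row data frame with Spearman/RMSE and CIs).
#' @export
run_subset_experiment <- function(features, labels, meta, spec,
                                  lambda2 = 1, k = 5L, seed = 1L,
                                  n_boot = 0L) {
  rows <- subset_rows(labels, meta, spec)
  n_img <- length(unique(rows$image_id))
  tag <- paste(c(spec$mode, spec$reader_ids, spec$label_rule), collapse = "-")
  if (n_img < spec$min_images) {
    return(list(excluded = TRUE, name = tag, n = n_img,
                reason = sprintf("subset has %d images, below the inclusion threshold %d",
                                 n_img, spec$min_images)))
  }
  pred <- cv_ridge_predict(features, rows, k = k, lambda2 = lambda2, seed = seed)
  pv <- pred[rows$image_id]
  list(excluded = FALSE, name = tag,
       predictions = data.frame(image_id = rows$image_id, prediction = pv,
                                label = rows$label, stringsAsFactors = FALSE,
                                row.names = NULL),
       metrics = metric_row(tag, pv, rows$label, n_boot = n_boot, seed = seed))
}

#' Train/test grid over averaged and individual labels
#'
#' The four-cell baseline: training on averaged (Av) or individual (Ind)
#' labels crossed with testing on averaged or individual labels. Individual
#' training uses each (image, reader score) pair as its own training row;
#' individual testing evaluates every image prediction against both of its
#' reader scores. Both models share the same subject-level fold plan, so
#' cell differences are label-driven.
#'
#' @inheritParams run_subset_experiment
#' @return Data frame of four metric rows named `"Tr-Ts"` (`Av-Av`,
#'   `Av-Ind`, `Ind-Av`, `Ind-Ind`).
#' @export
trts_grid <- function(features, labels, meta, lambda2 = 1, k = 5L,
                      seed = 1L, n_boot = 0L) {
  rows_av <- subset_rows(labels, meta, subset_spec("all", label_rule = "averaged"))
  rows_ind <- subset_rows(labels, meta, subset_spec("all", label_rule = "individual"))
  pred_av <- cv_ridge_predict(features, rows_av, k = k, lambda2 = lambda2, seed = seed)
  pred_ind <- cv_ridge_predict(features, rows_ind, k = k, lambda2 = lambda2, seed = seed)
  cells <- list(
    `Av-Av` = list(p = pred_av[rows_av$image_id], y = rows_av$label),
    `Av-Ind` = list(p = pred_av[rows_ind$image_id], y = rows_ind$label),
    `Ind-Av` = list(p = pred_ind[rows_av$image_id], y = rows_av$label),
    `Ind-Ind` = list(p = pred_ind[rows_ind$image_id], y = rows_ind$label)
  )
  out <- do.call(rbind, lapply(names(cells), function(nm) {
    metric_row(nm, cells[[nm]]$p, cells[[nm]]$y, n_boot = n_boot,
               seed = child_seed(seed, match(nm, names(cells))))
  }))
  rownames(out) <- NULL
  out
}

#' Per-reader subset experiments with Av1/Av2 aggregates
#'
#' Runs an individual-label mapping experiment for every reader meeting the
#' inclusion threshold and aggregates the per-reader metrics as Av1 (mean
#' across readers, SD as uncertainty) and Av2 (metric recomputed on the
#' pooled prediction/label pairs).
#'
#' @inheritParams run_subset_experiment
#' @param min_images Inclusion threshold on images per reader.
#' @return List: `per_reader` (metric row per included reader), `excluded`
#'   (ids of readers below threshold), `av1_rank`, `av2_rank`, `av1_rmse`,
#'   `av2_rmse`, and `pooled` predictions.
#' @export
per_reader_experiments <- function(features, labels, meta, lambda2 = 1,
                                   k = 5L, seed = 1L, min_images = 400L,
                                   n_boot = 0L) {
  readers <- sort(unique(labels$reader_id))
  res <- lapply(readers, function(r) {
    run_subset_experiment(features, labels, meta,
                          subset_spec("individual", r, min_images = min_images),
                          lambda2 = lambda2, k = k, seed = seed)
  })
  names(res) <- readers
  included <- !vapply(res, `[[`, logical(1), "excluded")
  if (!any(included)) {
    return(list(per_reader = NULL, excluded = readers, pooled = NULL))
  }
  per_reader <- do.call(rbind, lapply(res[included], `[[`, "metrics"))
  pooled <- do.call(rbind, lapply(res[included], `[[`, "predictions"))
  agg <- function(col, stat) {
    aggregate_reader_metrics(
      data.frame(metric = per_reader[[col]]),
      pooled$prediction, pooled$label, stat,
      n_boot = n_boot, seed = child_seed(seed, 31L))
  }
  rank_agg <- agg("rank_corr", spearman)
  rmse_agg <- agg("rmse", rmse)
  list(per_reader = per_reader,
       excluded = readers[!included],
       av1_rank = rank_agg$av1, av2_rank = rank_agg$av2,
       av1_rmse = rmse_agg$av1, av2_rmse = rmse_agg$av2,
       pooled = pooled)
}

#' Per-pair subset experiments with Av1/Av2 aggregates
#'
#' As [per_reader_experiments()] but over reader pairs: each subset holds
#' the images jointly scored by one pair, labelled with the pair average.
#'
#' @inheritParams per_reader_experiments
#' @return List with `per_pair`, `excluded`, the four aggregates, and
#'   `pooled` predictions.
#' @export
per_pair_experiments <- function(features, labels, meta, lambda2 = 1,
                                 k = 5L, seed = 1L, min_images = 400L,
                                 n_boot = 0L) {
  by_img <- split(labels$reader_id, labels$image_id)
  pair_of <- vapply(by_img, function(r) paste(sort(r), collapse = "_"),
                    character(1))
  pairs <- sort(unique(pair_of))
  res <- lapply(pairs, function(p) {
    rid <- strsplit(p, "_", fixed = TRUE)[[1]]
    run_subset_experiment(features, labels, meta,
                          subset_spec("pair", rid, min_images = min_images),
                          lambda2 = lambda2, k = k, seed = seed)
  })
  names(res) <- pairs
  included <- !vapply(res, `[[`, logical(1), "excluded")
  if (!any(included)) {
    return(list(per_pair = NULL, excluded = pairs, pooled = NULL))
  }
  per_pair <- do.call(rbind, lapply(res[included], `[[`, "metrics"))
  pooled <- do.call(rbind, lapply(res[included], `[[`, "predictions"))
  agg <- function(col, stat) {
    aggregate_reader_metrics(
      data.frame(metric = per_pair[[col]]),
      pooled$prediction, pooled$label, stat,
      n_boot = n_boot, seed = child_seed(seed, 37L))
  }
  rank_agg <- agg("rank_corr", spearman)
  rmse_agg <- agg("rmse", rmse)
  list(per_pair = per_pair,
       excluded = pairs[!included],
       av1_rank = rank_agg$av1, av2_rank = rank_agg$av2,
       av1_rmse = rmse_agg$av1, av2_rmse = rmse_agg$av2,
       pooled = pooled)
}
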