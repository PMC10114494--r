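#' Spearman rank correlation
#'
#' Pearson correlation of the average-rank vectors. A constant input has no
#' defined rank ordering: the result is `NA` (an explicit undefined marker),
#' never silently 0.
#'
#' @param a,b Equal-length numeric vectors (length >= 3).
#' @return Coefficient in \[-1,1\], or `NA_real_` when undefined.
#' @export
spearman <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b, method = "spearman")
}

#' Root mean squared error
#'
#' @param a,b Equal-length numeric vectors.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  sqrt(mean((a - b)^2))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples image-level pairs with replacement `B` times and returns the
#' percentile interval of the statistic. Resamples on which the statistic is
#' undefined (`NA`, e.g. a constant resample under Spearman) are redrawn up
#' to a capped retry count; if the cap is exhausted the interval is
#' undefined (`NA` bounds). Deterministic for a fixed seed and independent
#' of the caller's RNG stream.
#'
#' @param a First paired vector (e.g. predictions).
#' @param b Second paired vector (e.g. labels); may be `NULL` for one-sample
#'   statistics.
#' @param stat Function of `(a, b)` (or of `a` alone when `b` is `NULL`)
#'   returning a scalar.
#' @param B Number of bootstrap repeats (default 1000).
#' @param level Coverage level (default 0.95).
#' @param seed Integer seed.
#' @param max_retry Cap on redraws of undefined resamples.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(a, b = NULL, stat, B = 1000L, level = 0.95,
                         seed = 1L, max_retry = 100L) {
  n <- length(a)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (!is.null(b) && length(b) != n) stop("a and b must align", call. = FALSE)
  eval_stat <- function(idx) {
    if (is.null(b)) stat(a[idx]) else stat(a[idx], b[idx])
  }
  with_seed(seed, {
    vals <- numeric(B)
    retries <- 0L
    for (r in seq_len(B)) {
      v <- eval_stat(sample.int(n, n, replace = TRUE))
      while (is.na(v) && retries < max_retry) {
        retries <- retries + 1L
        v <- eval_stat(sample.int(n, n, replace = TRUE))
      }
      vals[r] <- v
    }
    if (anyNA(vals)) return(c(low = NA_real_, high = NA_real_))
    alpha <- (1 - level) / 2
    q <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE)
    c(low = q[1], high = q[2])
  })
}

# Metric pair (Spearman + RMSE) with optional bootstrap CIs, as one row of a
# metrics report.
metric_row <- function(name, pred, label, n_boot = 0L, seed = 1L) {
  rc <- spearman(pred, label)
  rm <- rmse(pred, label)
  out <- data.frame(name = name, n = length(pred),
                    rank_corr = rc, rank_corr_low = NA_real_,
                    rank_corr_high = NA_real_,
                    rmse = rm, rmse_low = NA_real_, rmse_high = NA_real_,
                    stringsAsFactors = FALSE)
  if (n_boot > 0L) {
    ci_rc <- bootstrap_ci(pred, label, spearman, B = n_boot,
                          seed = child_seed(seed, 11L))
    ci_rm <- bootstrap_ci(pred, label, rmse, B = n_boot,
                          seed = child_seed(seed, 12L))
    out$rank_corr_low <- ci_rc[["low"]]; out$rank_corr_high <- ci_rc[["high"]]
    out$rmse_low <- ci_rm[["low"]]; out$rmse_high <- ci_rm[["high"]]
  }
  out
}

#' Reader-level metric aggregates Av1 and Av2
#'
#' `Av1` is the unweighted mean of the per-reader metric values with the
#' between-reader standard deviation as its uncertainty. `Av2` recomputes
#' the metric on the concatenation of all per-reader prediction/label pairs
#' (repeated image-score pairs included), with a bootstrap CI; it is not in
#' general a weighted mean of the per-reader metrics.
#'
#' @param per_reader Data frame with one row per reader and a numeric
#'   `metric` column (plus optional `n`).
#' @param pooled_pred,pooled_label The concatenated prediction/label pairs
#'   across readers.
#' @param stat Metric function of `(pred, label)` (e.g. [spearman] or
#'   [rmse]).
#' @param n_boot Bootstrap repeats for the Av2 interval (0 disables).
#' @param seed Integer seed for the bootstrap.
#' @return List with `av1` (`value`, `sd`) and `av2` (`value`, `low`,
#'   `high`, `n`).
#' @export
aggregate_reader_metrics <- function(per_reader, pooled_pred, pooled_label,
                                     stat, n_boot = 1000L, seed = 1L) {
  if (nrow(per_reader) < 1L) stop("need at least one reader", call. = FALSE)
  av1 <- mean(per_reader$metric)
  av1_sd <- if (nrow(per_reader) > 1L) stats::sd(per_reader$metric) else 0
  av2 <- stat(pooled_pred, pooled_label)
  ci <- if (n_boot > 0L) {
    bootstrap_ci(pooled_pred, pooled_label, stat, B = n_boot, seed = seed)
  } else {
    c(low = NA_real_, high = NA_real_)
  }
  list(av1 = c(value = av1, sd = av1_sd),
       av2 = c(value = av2, low = ci[["low"]], high = ci[["high"]],
               n = length(pooled_pred)))
}

#' Top-versus-bottom quintile odds ratio
#'
#' Quintile boundaries are taken from the control score distribution; the
#' odds ratio compares the case/control odds in the highest quintile with
#' the lowest. The CI uses the normal approximation on the log odds ratio;
#' when any cell is zero the Haldane-Anscombe 0.5 correction is applied and
#' flagged.
#'
#' @param scores Per-subject density scores (predictions or labels).
#' @param is_case Logical case indicator aligned with `scores`.
#' @param level CI level (default 0.95).
#' @return List with `or`, `low`, `high`, `corrected` (logical flag) and the
#'   2x2 `cells` (cases/controls in top and bottom quintiles).
#' @export
quintile_odds_ratio <- function(scores, is_case, level = 0.95) {
  is_case <- as.logical(is_case)
  if (!any(is_case) || !any(!is_case)) {
    stop("need both cases and controls", call. = FALSE)
  }
  ctrl <- scores[!is_case]
  if (length(unique(ctrl)) < 5L) {
    stop("control scores are too discrete to define quintiles", call. = FALSE)
  }
  br <- stats::quantile(ctrl, probs = seq(0, 1, 0.2))
  if (anyDuplicated(br)) {
    stop("degenerate control score distribution: duplicated quintile boundaries",
         call. = FALSE)
  }
  q <- cut(scores, breaks = br, include.lowest = TRUE, labels = FALSE)
  q[scores < br[1]] <- 1L
  q[scores > br[6]] <- 5L
  cells <- c(case_top = sum(is_case & q == 5L, na.rm = TRUE),
             ctrl_top = sum(!is_case & q == 5L, na.rm = TRUE),
             case_bot = sum(is_case & q == 1L, na.rm = TRUE),
             ctrl_bot = sum(!is_case & q == 1L, na.rm = TRUE))
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[["case_top"]] / cc[["ctrl_top"]]) /
    (cc[["case_bot"]] / cc[["ctrl_bot"]])
  se <- sqrt(sum(1 / cc))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = or, low = or * exp(-z * se), high = or * exp(z * se),
       corrected = corrected, cells = cells)
}
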