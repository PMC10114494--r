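#' Preprocessing configuration
#'
#' The standardization chain applied to every image before feature
#' extraction or end-to-end training, in this order: resize to
#' `target_size`, mirror left-laterality images to the right, clip
#' intensities to the (`clip_low`, `clip_high`) percentiles, invert,
#' histogram-equalize, and rescale to \[0,1\].
#'
#' @param target_size Output side length in pixels (default 224).
#' @param clip_low,clip_high Clipping percentiles, `0 <= low < high <= 100`.
#' @param n_equalization_bins Number of gray levels used by global histogram
#'   equalization.
#' @param invert Whether to invert intensities after clipping.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_size = 224L, clip_low = 1,
                              clip_high = 99, n_equalization_bins = 256L,
                              invert = TRUE) {
  assert_scalar_number(target_size, "target_size", lo = 16)
  assert_scalar_number(clip_low, "clip_low", lo = 0, hi = 100)
  assert_scalar_number(clip_high, "clip_high", lo = 0, hi = 100)
  if (clip_low >= clip_high) stop("clip_low must be < clip_high", call. = FALSE)
  assert_scalar_number(n_equalization_bins, "n_equalization_bins", lo = 2)
  structure(list(target_size = as.integer(target_size),
                 clip_low = clip_low, clip_high = clip_high,
                 n_equalization_bins = as.integer(n_equalization_bins),
                 invert = isTRUE(invert)),
            class = "preprocess_config")
}

#' Standardize one image
#'
#' Applies the full preprocessing chain (see [preprocess_config()]).
#' Constant (degenerate) inputs pass through as a constant grid without
#' numeric failure. Deterministic.
#'
#' @param pixels Numeric matrix of intensities, or a `SyntheticImage`-style
#'   list with a `pixels` field.
#' @param config A [preprocess_config()].
#' @param laterality `"L"` or `"R"`; left images are mirrored so all breasts
#'   point the same way.
#' @return `target_size` x `target_size` matrix with values in \[0,1\].
#' @export
preprocess_image <- function(pixels, config = preprocess_config(),
                             laterality = "R") {
  if (is.list(pixels) && !is.null(pixels$pixels)) pixels <- pixels$pixels
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stop("`pixels` must be a non-empty numeric matrix", call. = FALSE)
  }
  ts <- config$target_size
  x <- if (all(dim(pixels) == c(ts, ts))) pixels else
    as.matrix(EBImage::resize(pixels, w = ts, h = ts))
  if (identical(laterality, "L")) x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
  lo <- as.numeric(stats::quantile(x, config$clip_low / 100))
  hi <- as.numeric(stats::quantile(x, config$clip_high / 100))
  x <- clip(x, lo, hi)
  if (config$invert) x <- (lo + hi) - x
  rng <- range(x)
  if (rng[2] > rng[1]) {
    x <- equalize_hist(x, config$n_equalization_bins)
    rng <- range(x)
    if (rng[2] > rng[1]) x <- (x - rng[1]) / (rng[2] - rng[1])
  } else {
    x[] <- clip(rng[1], 0, 1)
  }
  x
}

# Global histogram equalization: map intensities through their binned
# empirical CDF on `n_bins` gray levels.
equalize_hist <- function(x, n_bins) {
  rng <- range(x)
  b <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins), n_bins - 1L)
  cdf <- cumsum(tabulate(b + 1L, nbins = n_bins)) / length(x)
  matrix(cdf[b + 1L], nrow(x), ncol(x))
}

#' Preprocess every image of a cohort
#'
#' @param cohort A `density_cohort`.
#' @param config A [preprocess_config()].
#' @return Named list of standardized matrices, aligned with
#'   `cohort$meta$image_id`; left-laterality views are mirrored per the
#'   chain.
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config()) {
  out <- vector("list", nrow(cohort$meta))
  for (i in seq_len(nrow(cohort$meta))) {
    out[[i]] <- preprocess_image(cohort$images[[i]], config,
                                 laterality = cohort$meta$laterality[i])
  }
  names(out) <- cohort$meta$image_id
  out
}
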