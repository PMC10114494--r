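#' Simulated reader profile
#'
#' One simulated expert reader, parameterized by the three components of
#' inter-reader variability: a systematic, image-dependent offset (weights
#' on the image texture attributes), a strictly monotone distribution warp
#' of the VAS scale, and zero-mean random error.
#'
#' The warp is a scaled Beta CDF, `w(x) = 100 * pbeta(x/100, a, b)`: it is
#' strictly increasing on \[0,100\] and fixes both endpoints, so two readers
#' differing only in warp agree on the ranking of images while recording
#' different absolute values.
#'
#' @param reader_id Identifier string.
#' @param warp_shape Length-2 positive vector `(a, b)` of the Beta-CDF warp;
#'   `c(1, 1)` is the identity.
#' @param bias_weights Numeric weights applied to the image texture
#'   attributes (systematic per-reader bias); length must match the cohort's
#'   texture-attribute dimension (3 by default).
#' @param noise_sd Standard deviation (VAS points) of the additive random
#'   error.
#' @param workload_weight Non-negative sampling weight for pragmatic reader
#'   assignment.
#' @return Object of class `reader_profile`.
#' @export
reader_profile <- function(reader_id,
                           warp_shape = c(1, 1),
                           bias_weights = c(0, 0, 0),
                           noise_sd = 0,
                           workload_weight = 1) {
  if (length(warp_shape) != 2L || any(warp_shape <= 0)) {
    stop("`warp_shape` must be two positive Beta shape parameters",
         call. = FALSE)
  }
  assert_scalar_number(noise_sd, "noise_sd", lo = 0)
  assert_scalar_number(workload_weight, "workload_weight", lo = 0)
  structure(list(
    reader_id = as.character(reader_id),
    warp_shape = as.numeric(warp_shape),
    bias_weights = as.numeric(bias_weights),
    noise_sd = noise_sd,
    workload_weight = workload_weight
  ), class = "reader_profile")
}

#' Apply a reader's monotone scale warp
#'
#' @param profile A [reader_profile()].
#' @param x Densities in \[0,100\].
#' @return Warped values in \[0,100\].
#' @export
reader_warp <- function(profile, x) {
  100 * stats::pbeta(x / 100, profile$warp_shape[1], profile$warp_shape[2])
}

#' Generate a pool of simulated readers
#'
#' Draws `m` readers whose warp shapes, bias weights and workloads vary
#' across the pool, emulating a reading panel with distinct scoring
#' behaviour. Warp shapes are log-normal around the identity with spread
#' `warp_spread`; bias weights are normal with SD `bias_sd` VAS points per
#' standardized texture unit; workload weights are gamma-distributed so a
#' few heavy readers dominate and heavy reader pairs co-occur.
#'
#' @param m Number of readers (default 13, the included-panel size).
#' @param seed Integer seed.
#' @param noise_sd Random-error SD shared by all readers (VAS points).
#' @param warp_spread SD of the log warp-shape parameters; 0 gives identity
#'   warps.
#' @param bias_sd SD of the texture bias weights; 0 disables systematic
#'   bias.
#' @param n_texture Length of the texture-attribute vector.
#' @return List of [reader_profile()] objects named by reader id (A, B, ...).
#' @export
reader_pool <- function(m = 13L, seed = 1L, noise_sd = 8,
                        warp_spread = 0.5, bias_sd = 3, n_texture = 3L) {
  if (m < 1L) stop("`m` must be at least 1", call. = FALSE)
  with_seed(seed, {
    ids <- make.unique(rep(LETTERS, length.out = m), sep = "")
    lapply(seq_len(m), function(i) {
      reader_profile(
        reader_id = ids[i],
        warp_shape = exp(stats::rnorm(2, 0, warp_spread)),
        bias_weights = stats::rnorm(n_texture, 0, bias_sd),
        noise_sd = noise_sd,
        workload_weight = stats::rgamma(1, shape = 1.3, rate = 1) + 0.1
      )
    }) -> pool
    names(pool) <- ids
    pool
  })
}

#' Simulate one reader's VAS score for one image
#'
#' The score is `clip(warp(true_density) + bias_weights . texture + noise)`,
#' the sum of the three variability components, clipped to the bounded VAS
#' scale \[0,100\] after noise is added.
#'
#' @param profile A [reader_profile()].
#' @param image A single-row slice of a cohort's `meta` data frame (or any
#'   list with `true_density` and `tx_*` texture entries).
#' @param seed Optional seed for the random-error draw.
#' @return Score in \[0,100\].
#' @export
simulate_reader_score <- function(profile, image, seed = NULL) {
  tx <- unlist(image[grep("^tx_", names(image))], use.names = FALSE)
  if (length(tx) != length(profile$bias_weights)) {
    stop(sprintf("texture attributes (length %d) do not match bias_weights (length %d)",
                 length(tx), length(profile$bias_weights)), call. = FALSE)
  }
  with_seed(seed, {
    raw <- reader_warp(profile, image$true_density) +
      sum(profile$bias_weights * tx) +
      stats::rnorm(1, 0, profile$noise_sd)
    clip(raw, 0, 100)
  })
}

# Vectorized scoring of many images by one reader (one noise draw per image).
score_images <- function(profile, meta) {
  tx <- as.matrix(meta[, grep("^tx_", names(meta)), drop = FALSE])
  raw <- reader_warp(profile, meta$true_density) +
    as.numeric(tx %*% profile$bias_weights) +
    stats::rnorm(nrow(meta), 0, profile$noise_sd)
  clip(raw, 0, 100)
}

#' Assign two readers to every image and simulate their scores
#'
#' Mirrors pragmatic panel assignment: each image is read by one pair of
#' distinct readers, drawn with probability proportional to the product of
#' the two readers' workload weights times a per-pair rota affinity
#' (log-normal, spread `affinity_sd`) that models readers working in
#' partially fixed partnerships. Each assigned reader then produces a score
#' via the three-component reader model. Heavy, high-affinity pairs co-occur
#' often, creating the per-pair subsets used downstream; setting
#' `affinity_sd = 0` reduces to independent workload-weighted pairing.
#'
#' @param cohort A `density_cohort`.
#' @param readers List of [reader_profile()]s (at least two with positive
#'   workload weight).
#' @param seed Integer seed.
#' @param affinity_sd Log-SD of the rota affinity factor (default 1.5).
#' @return Long-format label table: data frame with columns `image_id`,
#'   `reader_id`, `score`; exactly two rows per image with distinct readers.
#' @export
assign_reader_pairs <- function(cohort, readers, seed = 1L,
                                affinity_sd = 1.5) {
  w <- vapply(readers, function(r) r$workload_weight, numeric(1))
  ids <- vapply(readers, function(r) r$reader_id, character(1))
  if (sum(w > 0) < 2L) {
    stop("need at least two readers with positive workload_weight",
         call. = FALSE)
  }
  meta <- cohort$meta
  n <- nrow(meta)
  if (n == 0L) {
    return(data.frame(image_id = character(), reader_id = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    prs <- t(utils::combn(length(readers), 2L))
    q <- w[prs[, 1]] * w[prs[, 2]] *
      exp(stats::rnorm(nrow(prs), 0, affinity_sd))
    pair_idx <- prs[sample.int(nrow(prs), n, replace = TRUE, prob = q), ,
                    drop = FALSE]
    # randomize within-pair order so neither reader is systematically first
    swap <- stats::runif(n) < 0.5
    pair_idx[swap, ] <- pair_idx[swap, c(2L, 1L)]
    # one independent noise stream per reader, drawn in reader order so the
    # table is reproducible regardless of assignment pattern
    scores <- matrix(NA_real_, n, 2L)
    for (r in seq_along(readers)) {
      sel <- pair_idx == r
      rows <- which(rowSums(sel) > 0)
      if (!length(rows)) next
      s <- score_images(readers[[r]], meta[rows, , drop = FALSE])
      scores[cbind(rows, max.col(sel[rows, , drop = FALSE], "first"))] <- s
    }
    data.frame(
      image_id = rep(meta$image_id, each = 2L),
      reader_id = ids[as.vector(t(pair_idx))],
      score = as.vector(t(scores)),
      stringsAsFactors = FALSE
    )
  })
}
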