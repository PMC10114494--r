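#' Cohort generator configuration
#'
#' Parameters controlling the synthetic screening cohort: each subject
#' (woman) contributes up to four mammogram-like views (RCC, LCC, RMLO,
#' LMLO) sharing one subject-level latent density with small per-view
#' jitter. Images are grayscale grids in \[0,1\] carrying dense-tissue blobs
#' on a darker half-elliptical breast mask; the ground-truth density of an
#' image is the percentage of the mask area covered by dense blobs, so the
#' density signal is both visually and statistically present.
#'
#' @param n_subjects Number of subjects (women); each yields 4 views minus
#'   any configured missing-view rate.
#' @param image_size Side length in pixels of the square generated images
#'   (minimum 16).
#' @param within_subject_sd Standard deviation (VAS points) of the per-view
#'   jitter around the subject-level density target.
#' @param missing_view_rate Probability that any given view is absent.
#' @param density_shape Two positive shape parameters of the Beta
#'   distribution (scaled to \[0,100\]) from which subject densities are
#'   drawn; the default Beta(2, 3.5) is right-skewed like a screening
#'   population.
#' @param blob_amp_range Range of the per-image brightness amplitude of
#'   dense tissue; the jitter keeps raw mean intensity an informative but
#'   imperfect proxy of true density.
#' @param pixel_noise_sd Standard deviation of additive per-pixel intensity
#'   noise.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects,
                          image_size = 64L,
                          within_subject_sd = 2,
                          missing_view_rate = 0,
                          density_shape = c(2, 3.5),
                          blob_amp_range = c(0.45, 0.8),
                          pixel_noise_sd = 0.02) {
  assert_scalar_number(n_subjects, "n_subjects", lo = 0)
  assert_scalar_number(image_size, "image_size", lo = 16)
  assert_scalar_number(within_subject_sd, "within_subject_sd", lo = 0)
  assert_scalar_number(missing_view_rate, "missing_view_rate", lo = 0, hi = 1)
  if (length(density_shape) != 2L || any(density_shape <= 0)) {
    stop("`density_shape` must be two positive Beta shape parameters",
         call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    image_size = as.integer(image_size),
    within_subject_sd = within_subject_sd,
    missing_view_rate = missing_view_rate,
    density_shape = density_shape,
    blob_amp_range = blob_amp_range,
    pixel_noise_sd = pixel_noise_sd
  ), class = "cohort_config")
}

# Half-elliptical breast mask with the chest wall on the left edge (the
# canonical right-laterality orientation; left images are mirrored).
breast_mask <- function(size) {
  x <- (col(matrix(0, size, size)) - 1) / (size - 1)
  y <- (row(matrix(0, size, size)) - 1) / (size - 1)
  (x / 0.88)^2 + ((y - 0.5) / 0.44)^2 <= 1
}

# Render one image: accumulate Gaussian-profile blobs until the covered
# fraction of the mask reaches `target_frac`. Returns pixels, the achieved
# coverage (the exact ground truth) and texture descriptors.
render_image <- function(size, target_frac, mask, mask_idx, amp,
                         pixel_noise_sd, cluster_prob = 0.35) {
  dense <- matrix(0, size, size)
  covered <- matrix(FALSE, size, size)
  n_mask <- length(mask_idx)
  centers <- NULL
  n_blobs <- 0L
  n_clustered <- 0L
  radii <- numeric(0)
  r_lo <- max(1.5, size * 0.03)
  r_hi <- size * 0.09
  max_iter <- 600L
  while (sum(covered) / n_mask < target_frac && n_blobs < max_iter) {
    r <- stats::runif(1, r_lo, r_hi)
    clustered <- !is.null(centers) && stats::runif(1) < cluster_prob
    if (clustered) {
      base <- centers[sample.int(nrow(centers), 1L), ]
      cen <- round(base + stats::rnorm(2, sd = 1.5 * r))
      cen <- clip(cen, 1, size)
      if (!mask[cen[1], cen[2]]) clustered <- FALSE
    }
    if (!clustered) {
      k <- mask_idx[sample.int(n_mask, 1L)]
      cen <- c((k - 1L) %% size + 1L, (k - 1L) %/% size + 1L)
    } else {
      n_clustered <- n_clustered + 1L
    }
    i0 <- max(1L, floor(cen[1] - 2 * r)); i1 <- min(size, ceiling(cen[1] + 2 * r))
    j0 <- max(1L, floor(cen[2] - 2 * r)); j1 <- min(size, ceiling(cen[2] + 2 * r))
    di <- (i0:i1) - cen[1]
    dj <- (j0:j1) - cen[2]
    d2 <- outer(di^2, dj^2, `+`)
    prof <- exp(-d2 / (2 * (r / 1.7)^2))
    sub_mask <- mask[i0:i1, j0:j1]
    prof[!sub_mask] <- 0
    dense[i0:i1, j0:j1] <- pmax(dense[i0:i1, j0:j1], prof)
    covered[i0:i1, j0:j1] <- covered[i0:i1, j0:j1] | (d2 <= r^2 & sub_mask)
    centers <- rbind(centers, cen)
    n_blobs <- n_blobs + 1L
    radii <- c(radii, r)
  }
  coverage <- sum(covered) / n_mask
  px <- matrix(0.03, size, size)
  px[mask] <- 0.22
  px <- px + amp * dense * as.numeric(mask)
  px <- px + matrix(stats::rnorm(size * size, sd = pixel_noise_sd), size, size)
  px <- clip(px, 0, 1)
  # standardized texture descriptors used by the systematic reader bias
  list(
    pixels = px,
    coverage = coverage,
    texture = c(
      tx_blobs = (n_blobs - 20) / 15,
      tx_radius = (if (n_blobs > 0) mean(radii) else r_lo) / size * 20 - 1.2,
      tx_cluster = (if (n_blobs > 0) n_clustered / n_blobs else 0) - 0.35
    )
  )
}

#' Generate a synthetic screening cohort
#'
#' Draws subject-level densities from the configured right-skewed Beta
#' distribution, renders four views per subject (RCC/LCC/RMLO/LMLO, minus
#' the missing-view rate) and records per-image ground-truth density (the
#' achieved dense-tissue coverage, in \[0,100\]) together with texture
#' descriptors that drive systematic reader bias. Bit-identical for a fixed
#' seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return An object of class `density_cohort`: a list with `images` (named
#'   list of matrices in \[0,1\]), `meta` (data frame: `image_id`,
#'   `subject_id`, `view`, `laterality`, `true_density`, `tx_*` texture
#'   columns), `subjects` (data frame: `subject_id`, `density`, `age`) and
#'   the `config`.
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    n <- config$n_subjects
    size <- config$image_size
    subjects <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      density = 100 * stats::rbeta(n, config$density_shape[1],
                                   config$density_shape[2]),
      age = round(stats::runif(n, 47, 73)),
      stringsAsFactors = FALSE
    )
    if (n == 0L) {
      return(structure(list(
        images = list(),
        meta = data.frame(image_id = character(), subject_id = character(),
                          view = character(), laterality = character(),
                          true_density = numeric(), tx_blobs = numeric(),
                          tx_radius = numeric(), tx_cluster = numeric(),
                          stringsAsFactors = FALSE),
        subjects = subjects, config = config
      ), class = "density_cohort"))
    }
    mask <- breast_mask(size)
    mask_idx <- which(mask)
    views <- data.frame(view = rep(c("CC", "CC", "MLO", "MLO"), n),
                        laterality = rep(c("R", "L", "R", "L"), n))
    views$subject_id <- rep(subjects$subject_id, each = 4L)
    views$target <- clip(rep(subjects$density, each = 4L) +
                           stats::rnorm(nrow(views), 0, config$within_subject_sd),
                         0, 100)
    keep <- stats::runif(nrow(views)) >= config$missing_view_rate
    views <- views[keep, , drop = FALSE]
    images <- vector("list", nrow(views))
    meta_rows <- vector("list", nrow(views))
    for (i in seq_len(nrow(views))) {
      amp <- stats::runif(1, config$blob_amp_range[1], config$blob_amp_range[2])
      rendered <- render_image(size, views$target[i] / 100, mask, mask_idx,
                               amp, config$pixel_noise_sd)
      img_id <- sprintf("%s_%s%s", views$subject_id[i], views$laterality[i],
                        views$view[i])
      images[[i]] <- rendered$pixels
      meta_rows[[i]] <- data.frame(
        image_id = img_id,
        subject_id = views$subject_id[i],
        view = views$view[i],
        laterality = views$laterality[i],
        true_density = 100 * rendered$coverage,
        tx_blobs = rendered$texture[["tx_blobs"]],
        tx_radius = rendered$texture[["tx_radius"]],
        tx_cluster = rendered$texture[["tx_cluster"]],
        stringsAsFactors = FALSE
      )
    }
    meta <- do.call(rbind, meta_rows)
    names(images) <- meta$image_id
    structure(list(images = images, meta = meta, subjects = subjects,
                   config = config),
              class = "density_cohort")
  })
}

#' @export
print.density_cohort <- function(x, ...) {
  cat(sprintf("density_cohort: %d images from %d subjects (%dx%d px)\n",
              nrow(x$meta), nrow(x$subjects), x$config$image_size,
              x$config$image_size))
  invisible(x)
}

#' Extract the texture-attribute matrix of a cohort
#'
#' @param cohort A `density_cohort`.
#' @return Numeric matrix (one row per image) of standardized texture
#'   descriptors, in `meta` row order.
#' @export
texture_attributes <- function(cohort) {
  as.matrix(cohort$meta[, c("tx_blobs", "tx_radius", "tx_cluster")])
}
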